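#' Generate a synthetic IMGT-style germline gene set
#'
#' Builds a fully synthetic human-IGH-like germline reference for testing
#' and simulation: no sequence is a real IMGT allele. V genes are 285 nt
#' (95 codons) of stop-free coding sequence carrying the conserved
#' 1st-CYS (gapped codon 23), hallmark W (gapped codon 41) and 2nd-CYS
#' (gapped codon 104, the CDR3 anchor); their `gapped_sequence` inserts
#' IMGT-style gaps (dots) at codons 31-35 and 60-65 so gapped-anchor
#' derivation is exercised. Genes within a subgroup diverge ~8\% from a
#' subgroup consensus; subgroups are independent draws. J genes are 42 nt
#' with the J-TRP anchor at position 9 followed by a W-G-x-G FR4 motif;
#' D genes are 14-26 nt of random sequence. Gene names follow IMGT
#' nomenclature style (e.g. `IGHV3-30*01`) but label synthetic sequences.
#'
#' @param n_v,n_d,n_j Number of V, D and J genes (defaults 8, 6, 4).
#' @param seed Integer seed; the set is fully determined by it.
#' @return A merged `germline_set` tibble with provenance
#'   `"synthetic_germline_set seed=<seed>"`.
#' @examples
#' ref <- synthetic_germline_set(seed = 42)
#' table(ref$segment_class)
#' @export
synthetic_germline_set <- function(n_v = 8L, n_d = 6L, n_j = 4L, seed = 42L) {
  stopifnot(n_v >= 1L, n_d >= 1L, n_j >= 1L)
  withr_seed(seed)

  v_names <- c("IGHV1-18*01", "IGHV1-69*01", "IGHV3-7*01", "IGHV3-23*01",
               "IGHV3-30*01", "IGHV4-34*01", "IGHV4-59*01", "IGHV2-5*01",
               "IGHV5-51*01", "IGHV6-1*01",
               paste0("IGHV7-", seq_len(max(0L, n_v - 10L)), "*01"))
  v_names <- v_names[seq_len(n_v)]
  subgroups <- ighv_subgroup(strip_allele(v_names))
  consensus <- list()
  v_rows <- purrr::map2(v_names, subgroups, function(nm, sg) {
    if (is.null(consensus[[sg]])) {
      consensus[[sg]] <<- random_v_codons()
    }
    codons <- diverge_v_codons(consensus[[sg]], rate = 0.08)
    build_v_gene(nm, codons)
  })
  v_set <- new_germline_set(dplyr::bind_rows(v_rows), provenance = "tmp")

  d_names <- paste0("IGHD", rep(1:6, length.out = n_d), "-",
                    seq_len(n_d), "*01")
  d_rows <- purrr::map(d_names, function(nm) {
    len <- sample(14:26, 1L)
    tibble::tibble(
      name = nm, gene_name = strip_allele(nm),
      subgroup = ighv_subgroup(strip_allele(nm)),
      segment_class = "D",
      sequence = random_dna(len),
      gapped_sequence = NA_character_, anchor = NA_integer_
    )
  })
  d_set <- new_germline_set(dplyr::bind_rows(d_rows), provenance = "tmp")

  j_names <- paste0("IGHJ", seq_len(n_j), "*01")
  j_rows <- purrr::map(j_names, function(nm) build_j_gene(nm))
  j_set <- new_germline_set(dplyr::bind_rows(j_rows), provenance = "tmp")

  out <- merge_germline_sets(v_set, d_set, j_set)
  attr(out, "provenance") <- paste0("synthetic_germline_set seed=", seed)
  out
}

# scoped RNG: seed the stream for the calling function only
withr_seed <- function(seed, envir = parent.frame()) {
  withr::local_seed(seed, .local_envir = envir)
  invisible(NULL)
}

BASES <- c("A", "C", "G", "T")
STOP_CODONS <- c("TAA", "TAG", "TGA")

random_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                                collapse = "")

random_codon <- function() {
  repeat {
    c3 <- paste(sample(BASES, 3L, replace = TRUE), collapse = "")
    if (!c3 %in% STOP_CODONS) return(c3)
  }
}

# 95 coding codons for the ungapped V gene; index here is the *real* codon
# index (gapped codons 31-35 and 60-65 are gaps, carried separately).
# Real codon 23 = 1st-CYS, 36 (gapped 41) = W, 93 (gapped 104) = 2nd-CYS.
V_CYS1 <- 23L
V_TRP <- 36L
V_CYS2 <- 93L
V_N_CODONS <- 95L

random_v_codons <- function() {
  codons <- vapply(seq_len(V_N_CODONS), function(i) random_codon(),
                   character(1))
  codons[V_CYS1] <- "TGT"
  codons[V_TRP] <- "TGG"
  codons[V_CYS2] <- "TGT"
  codons
}

diverge_v_codons <- function(codons, rate) {
  fixed <- c(V_CYS1, V_TRP, V_CYS2)
  flip <- which(stats::runif(length(codons)) < rate)
  flip <- setdiff(flip, fixed)
  codons[flip] <- vapply(flip, function(i) random_codon(), character(1))
  codons
}

# gapped layout: codons 1-30 real, 31-35 gap, 36-59 real, 60-65 gap,
# 66-106 real; 2nd-CYS is gapped codon 104 = real codon 93.
build_v_gene <- function(name, codons) {
  seq <- paste(codons, collapse = "")
  gapped <- paste0(
    paste(codons[1:30], collapse = ""),
    strrep(".", 15L),
    paste(codons[31:54], collapse = ""),
    strrep(".", 18L),
    paste(codons[55:95], collapse = "")
  )
  tibble::tibble(
    name = name, gene_name = strip_allele(name),
    subgroup = ighv_subgroup(strip_allele(name)),
    segment_class = "V", sequence = seq, gapped_sequence = gapped,
    anchor = (V_CYS2 - 1L) * 3L
  )
}

J_ANCHOR <- 9L
J_LENGTH <- 42L

build_j_gene <- function(name) {
  repeat {
    fr4 <- paste0("GG", sample(BASES, 1L),           # G
                  random_codon(),                    # x
                  "GG", sample(BASES, 1L),           # G
                  paste(vapply(1:7, function(i) random_codon(),
                               character(1)), collapse = ""))
    seq <- paste0(random_dna(J_ANCHOR), "TGG", fr4)
    anchor <- j_anchor_from_motif(seq)
    if (!is.na(anchor) && anchor == J_ANCHOR) break
  }
  tibble::tibble(
    name = name, gene_name = strip_allele(name),
    subgroup = ighv_subgroup(strip_allele(name)),
    segment_class = "J", sequence = seq,
    gapped_sequence = NA_character_, anchor = J_ANCHOR
  )
}
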