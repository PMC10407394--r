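#' Pairwise CDR3 nucleotide identity
#'
#' Global end-to-end alignment of two CDR3 nucleotide sequences under the
#' pipeline's fixed scheme (match +1, mismatch -1, gap open -4, gap extend
#' -1/base); identity is matches divided by alignment columns, in percent.
#' Symmetric in its arguments.
#'
#' @param a,b Non-empty DNA strings.
#' @return Identity in percent (0..100).
#' @export
cdr3_identity <- function(a, b) {
  if (is.na(a) || is.na(b) || nchar(a) == 0L || nchar(b) == 0L) {
    stop("cdr3_identity requires two non-empty sequences", call. = FALSE)
  }
  a <- toupper(a); b <- toupper(b)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(a),
    subject = Biostrings::DNAString(b),
    type = "global",
    substitutionMatrix = aln_submat(),
    gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT
  )
  global_identity_pct(Biostrings::nmatch(aln), Biostrings::nmismatch(aln),
                      nchar(a), nchar(b))
}

# every end-to-end alignment column consumes one base of each sequence
# (match/mismatch) or one base of exactly one (gap, END GAPS INCLUDED), so
# columns = la + lb - (matches + mismatches); computing it this way keeps
# end gaps in the denominator, which trimmed aligned strings would drop
global_identity_pct <- function(nmatch, nmismatch, la, lb) {
  cols <- la + lb - (nmatch + nmismatch)
  unname(nmatch / cols * 100)
}

# vectorised form: identity of `a` against each element of `bs`
cdr3_identity_many <- function(a, bs) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(toupper(bs)),
    subject = Biostrings::DNAString(toupper(a)),
    type = "global",
    substitutionMatrix = aln_submat(),
    gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT
  )
  global_identity_pct(Biostrings::nmatch(aln), Biostrings::nmismatch(aln),
                      nchar(bs), nchar(a))
}

#' CDR3 length compatibility under the clone rule
#'
#' Two CDR3s are length-compatible when their length difference, as a
#' percent of the longer one, does not exceed the policy threshold
#' (inclusive: exactly 5\% passes under the default).
#'
#' @param a,b Non-empty DNA strings.
#' @param policy A [clone_policy()].
#' @return Logical.
#' @export
length_compatible <- function(a, b, policy = clone_policy()) {
  policy <- as_clone_policy(policy)
  la <- nchar(a); lb <- nchar(b)
  stopifnot(la > 0L, lb > 0L)
  abs(la - lb) / max(la, lb) * 100 <= policy$cdr3_max_len_diff_pct
}

#' Group cells into clones by shared V gene and near-identical CDR3
#'
#' Cells belong to one clone when they use the same V gene (allele
#' stripped), every pair of their CDR3s differs in length by at most the
#' policy threshold, and every pair exceeds the policy identity threshold
#' (strict `>`). The "every pair" reading is complete linkage: clusters are
#' agglomerated only while all cross pairs remain compatible, merging the
#' pair of clusters with the highest mean cross-pair CDR3 identity first
#' (ties by input order), so the partition is deterministic and never
#' chains through intermediates.
#'
#' Clone calling is performed within each sample. By default only
#' productive records enter; records lacking a CDR3 (or excluded as
#' non-productive) are emitted as singletons flagged `unclustered`.
#'
#' @param rearr A mutation-profiled tibble from [profile_mutations()] (the
#'   columns `sample_id`, `v_gene`, `cdr3`, `productive`,
#'   `mutation_status`, `v_mutation_positions` are used).
#' @param policy A [clone_policy()].
#' @param productive_only Restrict clone membership to productive records
#'   (default `TRUE`).
#' @return `rearr` with columns `clone_id` (sample-scoped, e.g. `"S1_c3"`),
#'   `clone_size`, `clone_status` (`mutated` if any member is mutated),
#'   `intraclonal_diversity` (logical; `NA` for unclustered records) and
#'   `n_variants` added.
#' @export
call_clones <- function(rearr, policy = clone_policy(),
                        productive_only = TRUE) {
  policy <- as_clone_policy(policy)
  stopifnot(is.data.frame(rearr))
  rearr <- tibble::as_tibble(rearr)
  rearr$.row <- seq_len(nrow(rearr))

  eligible <- !is.na(rearr$cdr3) & nchar(rearr$cdr3) > 0 &
    !is.na(rearr$v_gene)
  if (productive_only) eligible <- eligible & !is.na(rearr$productive) &
      rearr$productive

  rearr$clone_id <- NA_character_
  rearr$clone_unclustered <- !eligible

  for (s in unique(rearr$sample_id)) {
    in_s <- which(rearr$sample_id == s & eligible)
    if (length(in_s) == 0L) next
    part <- clone_partition(rearr$v_gene[in_s], rearr$cdr3[in_s], policy)
    rearr$clone_id[in_s] <- paste0(s, "_c", part)
  }
  # unclustered records become sample-scoped singleton clones
  uncl <- which(is.na(rearr$clone_id))
  if (length(uncl) > 0L) {
    rearr$clone_id[uncl] <- paste0(rearr$sample_id[uncl], "_u",
                                   seq_along(uncl))
  }
  annotate_clone_columns(rearr)
}

# Complete-linkage agglomeration over the compatibility graph for one
# sample. Returns an integer cluster label per record, numbered by first
# appearance in input order.
clone_partition <- function(v_gene, cdr3, policy) {
  n <- length(v_gene)
  if (n == 1L) return(1L)
  same_v <- outer(v_gene, v_gene, "==")
  lens <- nchar(cdr3)
  len_ok <- outer(lens, lens, function(x, y) {
    abs(x - y) / pmax(x, y) * 100 <= policy$cdr3_max_len_diff_pct
  })
  ident <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    ks <- which(same_v[i, ] & len_ok[i, ] & seq_len(n) > i)
    if (length(ks) == 0L) next
    ident[i, ks] <- ident[ks, i] <- cdr3_identity_many(cdr3[i], cdr3[ks])
  }
  compat <- same_v & len_ok & ident > policy$cdr3_min_identity_pct
  diag(compat) <- TRUE

  clusters <- as.list(seq_len(n))
  repeat {
    m <- length(clusters)
    if (m == 1L) break
    best <- NULL
    best_mean <- -Inf
    for (i in seq_len(m - 1L)) {
      for (k in (i + 1L):m) {
        cross <- compat[clusters[[i]], clusters[[k]], drop = FALSE]
        if (all(cross)) {
          mi <- mean(ident[clusters[[i]], clusters[[k]]])
          if (mi > best_mean + 1e-12) {
            best_mean <- mi
            best <- c(i, k)
          }
        }
      }
    }
    if (is.null(best)) break
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  lab <- integer(n)
  for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
  # renumber by first appearance in input order
  first <- vapply(split(seq_len(n), lab), min, integer(1))
  match(lab, as.integer(names(sort(first))))
}

# clone_size / clone_status / intraclonal diversity columns
annotate_clone_columns <- function(rearr) {
  rearr |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::mutate(
      clone_size = dplyr::n(),
      clone_status = if (all(is.na(.data$mutation_status))) NA_character_
        else if (any(.data$mutation_status == "mutated", na.rm = TRUE))
          "mutated" else "unmutated",
      n_variants = clone_n_variants(.data$v_mutation_positions, .data$cdr3),
      intraclonal_diversity = .data$n_variants > 1L
    ) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$.row) |>
    dplyr::select(-".row")
}

# number of distinct (mutation-position-set, cdr3) patterns among members
clone_n_variants <- function(positions, cdr3) {
  sig <- paste(ifelse(is.na(positions), "", positions),
               ifelse(is.na(cdr3), "", cdr3), sep = "|")
  length(unique(sig))
}

#' Assess intraclonal diversity of called clones
#'
#' A clone shows intraclonal diversity when its members carry more than one
#' distinct full V-region mutation pattern, i.e. more than one distinct
#' (mutation-position-set, CDR3) pair — evidence of ongoing or divergent
#' hypermutation within the lineage. Singletons are never diverse.
#'
#' @param rearr A clone-called tibble from [call_clones()].
#' @return A per-clone tibble: `clone_id`, `sample_id`, `v_gene`,
#'   `clone_size`, `clone_status`, `n_variants`, `intraclonal_diversity`,
#'   `representative_cdr3` (first member in input order).
#' @export
summarize_clones <- function(rearr) {
  rearr |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(
      sample_id = dplyr::first(.data$sample_id),
      v_gene = dplyr::first(.data$v_gene),
      clone_size = dplyr::n(),
      clone_status = dplyr::first(.data$clone_status),
      n_variants = dplyr::first(.data$n_variants),
      intraclonal_diversity = dplyr::first(.data$intraclonal_diversity),
      representative_cdr3 = dplyr::first(.data$cdr3),
      .groups = "drop"
    )
}
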