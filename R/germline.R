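#' Read an IMGT-style germline gene reference from FASTA
#'
#' Loads germline IGHV, IGHD or IGHJ gene sequences from a FASTA file into a
#' germline-set tibble. Headers may be plain (`>IGHV3-30*01`) or IMGT
#' pipe-delimited (gene/allele name in the second `|` field). IMGT-gapped
#' sequences (dots marking numbering gaps) are accepted: the dots are
#' stripped into `sequence` and the gapped original is kept in
#' `gapped_sequence`.
#'
#' Anchor positions (0-based ungapped position of the first base of the
#' conserved codon) are derived where possible:
#' \itemize{
#'   \item V genes with an IMGT-gapped sequence covering gapped codon 104:
#'     the 2nd-CYS anchor is the ungapped position of that codon.
#'   \item J genes: the J-TRP/J-PHE anchor is located by scanning for the
#'     conserved W/F-G-x-G motif (TGG/TTT/TTC followed by glycine codons at
#'     offsets +3 and +9).
#'   \item Any gene present in the optional sidecar `anchors` TSV
#'     (columns `name`, `anchor`, 0-based) takes the sidecar value.
#' }
#' Genes for which no anchor can be derived keep `NA` and are listed in the
#' load report (`attr(x, "load_report")`).
#'
#' @param path Path to a FASTA file.
#' @param segment_class One of `"V"`, `"D"`, `"J"`.
#' @param anchors Optional path to a sidecar TSV with columns `name`,
#'   `anchor` (0-based codon start), or a data frame with those columns.
#' @param provenance Free-text source/version string recorded on the set and
#'   propagated into pipeline output headers. Defaults to the file path.
#'
#' @return A tibble of class `germline_set` with columns `name`, `gene_name`,
#'   `subgroup`, `segment_class`, `sequence`, `gapped_sequence`, `anchor`,
#'   and attributes `provenance` and `load_report`.
#' @seealso [merge_germline_sets()], [write_germline_fasta()],
#'   [synthetic_germline_set()]
#' @export
read_germline_fasta <- function(path, segment_class = c("V", "D", "J"),
                                anchors = NULL, provenance = NULL) {
  segment_class <- match.arg(segment_class)
  fa <- Biostrings::readBStringSet(path)
  if (length(fa) == 0L) {
    stop("empty germline FASTA: ", path, call. = FALSE)
  }
  headers <- names(fa)
  name <- purrr::map_chr(headers, parse_germline_header)
  dup <- name[duplicated(name)]
  if (length(dup) > 0L) {
    stop("duplicate germline gene name(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  raw <- toupper(as.character(fa))
  bad <- stringr::str_detect(raw, "[^ACGTN.]")
  if (any(bad)) {
    stop("non-DNA characters in germline record(s): ",
         paste(name[bad], collapse = ", "), call. = FALSE)
  }
  gapped <- ifelse(stringr::str_detect(raw, stringr::fixed(".")), raw,
                   NA_character_)
  seqs <- stringr::str_remove_all(raw, stringr::fixed("."))
  if (any(nchar(seqs) == 0L)) {
    stop("empty sequence for germline record(s): ",
         paste(name[nchar(seqs) == 0L], collapse = ", "), call. = FALSE)
  }

  genes <- tibble::tibble(
    name = unname(name),
    gene_name = strip_allele(name),
    subgroup = ighv_subgroup(strip_allele(name)),
    segment_class = segment_class,
    sequence = unname(seqs),
    gapped_sequence = unname(gapped),
    anchor = NA_integer_
  )

  if (segment_class == "V") {
    genes$anchor <- purrr::map2_int(genes$gapped_sequence, genes$sequence,
                                    v_anchor_from_gapped)
  } else if (segment_class == "J") {
    genes$anchor <- purrr::map_int(genes$sequence, j_anchor_from_motif)
  }

  genes <- apply_sidecar_anchors(genes, anchors)

  missing_anchor <- genes$name[is.na(genes$anchor) &
                                 genes$segment_class %in% c("V", "J")]
  new_germline_set(
    genes,
    provenance = provenance %||% paste0("file:", path),
    load_report = list(n_records = nrow(genes),
                       missing_anchor = missing_anchor)
  )
}

new_germline_set <- function(genes, provenance, load_report = list()) {
  out <- tibble::new_tibble(genes, class = "germline_set")
  attr(out, "provenance") <- provenance
  attr(out, "load_report") <- load_report
  out
}

# IMGT pipe-delimited headers carry the allele name in field 2
parse_germline_header <- function(h) {
  h <- stringr::str_trim(h)
  if (stringr::str_detect(h, stringr::fixed("|"))) {
    fields <- stringr::str_split_1(h, stringr::fixed("|"))
    if (length(fields) < 2L || !nzchar(stringr::str_trim(fields[2]))) {
      stop("malformed IMGT header: ", h, call. = FALSE)
    }
    return(stringr::str_trim(fields[2]))
  }
  stringr::str_split_1(h, "\\s+")[1]
}

strip_allele <- function(name) stringr::str_remove(name, "\\*.*$")

ighv_subgroup <- function(gene_name) {
  sg <- stringr::str_extract(gene_name, "^[A-Za-z]+[0-9]+")
  ifelse(is.na(sg), gene_name, sg)
}

# 2nd-CYS sits at IMGT gapped codon 104: the anchor is the number of
# non-gap characters preceding gapped position 310 (1-based).
v_anchor_from_gapped <- function(gapped, sequence) {
  if (is.na(gapped)) return(NA_integer_)
  codon_start <- 103L * 3L + 1L
  if (nchar(gapped) < codon_start + 2L) return(NA_integer_)
  chars <- stringr::str_split_1(gapped, "")
  if (any(chars[codon_start:(codon_start + 2L)] == ".")) return(NA_integer_)
  anchor <- sum(chars[seq_len(codon_start - 1L)] != ".")
  if (anchor + 3L > nchar(sequence)) return(NA_integer_)
  as.integer(anchor)
}

# J-TRP/J-PHE anchor: first position whose codon is W (TGG) or F (TTT/TTC)
# with glycine codons (GGN) at offsets +3 and +9 (the W/F-G-x-G motif).
j_anchor_from_motif <- function(sequence) {
  n <- nchar(sequence)
  if (n < 12L) return(NA_integer_)
  for (p in seq_len(n - 11L)) {
    codon <- substr(sequence, p, p + 2L)
    if (!codon %in% c("TGG", "TTT", "TTC")) next
    if (substr(sequence, p + 3L, p + 4L) != "GG") next
    if (substr(sequence, p + 9L, p + 10L) != "GG") next
    return(as.integer(p - 1L))
  }
  NA_integer_
}

apply_sidecar_anchors <- function(genes, anchors) {
  if (is.null(anchors)) return(genes)
  tab <- if (is.data.frame(anchors)) {
    tibble::as_tibble(anchors)
  } else {
    readr::read_tsv(anchors, col_types = readr::cols(
      name = readr::col_character(), anchor = readr::col_integer()
    ))
  }
  stopifnot(all(c("name", "anchor") %in% names(tab)))
  idx <- match(genes$name, tab$name)
  hit <- !is.na(idx)
  genes$anchor[hit] <- as.integer(tab$anchor[idx[hit]])
  bad <- hit & (genes$anchor < 0L | genes$anchor + 3L > nchar(genes$sequence))
  if (any(bad)) {
    stop("sidecar anchor outside sequence for: ",
         paste(genes$name[bad], collapse = ", "), call. = FALSE)
  }
  genes
}

#' Merge germline sets for different segment classes
#'
#' @param ... `germline_set` tibbles (typically one V, one D, one J set).
#' @return A single `germline_set` tibble; provenance strings are
#'   concatenated.
#' @export
merge_germline_sets <- function(...) {
  sets <- list(...)
  stopifnot(length(sets) >= 1L)
  merged <- dplyr::bind_rows(lapply(sets, function(s) {
    tibble::as_tibble(s)[, c("name", "gene_name", "subgroup", "segment_class",
                             "sequence", "gapped_sequence", "anchor")]
  }))
  dup <- merged$name[duplicated(merged$name)]
  if (length(dup) > 0L) {
    stop("germline name collision on merge: ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  }
  prov <- paste(unique(unlist(lapply(sets, attr, "provenance"))),
                collapse = "; ")
  reports <- lapply(sets, attr, "load_report")
  new_germline_set(merged, provenance = prov,
                   load_report = list(
                     n_records = nrow(merged),
                     missing_anchor = unique(unlist(
                       lapply(reports, `[[`, "missing_anchor")))))
}

#' Subset a germline set by segment class
#'
#' @param germlines A `germline_set` tibble.
#' @param segment_class `"V"`, `"D"` or `"J"`.
#' @return The rows of that class, as a `germline_set`.
#' @export
germline_segment <- function(germlines, segment_class) {
  out <- tibble::as_tibble(germlines)[
    tibble::as_tibble(germlines)$segment_class == segment_class, ]
  new_germline_set(out, provenance = attr(germlines, "provenance"))
}

#' Write a germline set back to FASTA
#'
#' Writes plain headers (`>name`). Records carrying an IMGT-gapped sequence
#' are written gapped (dots preserved) so that V anchors can be re-derived
#' on reload; ungapped records are written as-is. Round-trips with
#' [read_germline_fasta()] on names and (ungapped) sequences.
#'
#' @param germlines A `germline_set` tibble.
#' @param path Output FASTA path.
#' @param gapped Write the gapped sequence when present (default `TRUE`).
#' @return `path`, invisibly.
#' @export
write_germline_fasta <- function(germlines, path, gapped = TRUE) {
  txt <- if (gapped) {
    ifelse(is.na(germlines$gapped_sequence), germlines$sequence,
           germlines$gapped_sequence)
  } else {
    germlines$sequence
  }
  seqs <- Biostrings::BStringSet(txt)
  names(seqs) <- germlines$name
  Biostrings::writeXStringSet(seqs, path, width = 60L)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
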