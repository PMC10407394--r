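#' Count somatic mutations over the V-gene portion of one alignment
#'
#' Walks the stored V alignment column by column and counts every
#' difference to the germline — substitutions plus one per inserted or
#' deleted base — over the V-gene portion only, i.e. alignment columns whose
#' germline position lies before the 2nd-CYS anchor (the CDR3/N region is
#' never counted). Query `N` bases are excluded from both numerator and
#' denominator. The frequency denominator is the number of germline
#' positions covered (`aligned_len`).
#'
#' @param v One-row V assignment tibble (from [assign_v_gene()] or an
#'   annotated row) carrying `germ_aligned`, `query_aligned`, `g_start`,
#'   `q_start`.
#' @param v_anchor_germ 0-based germline position of the 2nd-CYS codon;
#'   columns at or beyond it are ignored. `NA` means count the whole
#'   aligned span.
#' @param leading_trim Number of leading germline positions to exclude
#'   (e.g. a primer-binding FR1 stretch). Default 0.
#' @param min_aligned_len Minimum covered germline span for a mutation call.
#' @return A one-row tibble: `n_diff`, `aligned_len`, `freq_pct`
#'   (unrounded), and `positions`, a single string encoding each difference
#'   as `pos:ref>alt` (0-based germline position; `-` marks a gap side),
#'   semicolon-separated, ordered by position.
#' @export
count_v_mutations <- function(v, v_anchor_germ = NA_integer_,
                              leading_trim = 0L, min_aligned_len = 50L) {
  cols <- alignment_columns(v$germ_aligned, v$query_aligned,
                            v$g_start, v$q_start)
  # assign each insertion column (no germline base) the germline position it
  # interrupts, so V-region bounds apply to inserted bases too
  g_fill <- cols$g_pos
  for (i in seq_along(g_fill)) {
    if (is.na(g_fill[i])) g_fill[i] <- if (i > 1L) g_fill[i - 1L] else v$g_start
  }
  keep <- g_fill >= leading_trim
  if (!is.na(v_anchor_germ)) keep <- keep & g_fill < v_anchor_germ
  keep <- keep & cols$q_base != "N"
  cols <- cols[keep, , drop = FALSE]

  aligned_len <- sum(!is.na(cols$g_pos))
  if (aligned_len < min_aligned_len) {
    stop("V span too short for mutation call (", aligned_len, " nt)",
         call. = FALSE)
  }
  diff <- cols$g_base != cols$q_base
  n_diff <- sum(diff)
  pos_str <- if (n_diff == 0L) "" else {
    d <- cols[diff, , drop = FALSE]
    key <- ifelse(is.na(d$g_pos),
                  paste0(g_fill[keep][diff], ".5"), as.character(d$g_pos))
    ord <- order(as.numeric(key))
    paste(paste0(ifelse(is.na(d$g_pos), "ins", d$g_pos)[ord], ":",
                 d$g_base[ord], ">", d$q_base[ord]), collapse = ";")
  }
  tibble::tibble(
    n_diff = as.integer(n_diff),
    aligned_len = as.integer(aligned_len),
    freq_pct = n_diff / aligned_len * 100,
    positions = pos_str
  )
}

#' Classify a mutation profile as mutated or unmutated
#'
#' A cell is unmutated when its V gene differs from the germline by at most
#' `policy$unmutated_max_diff` nucleotides (default 1: a single difference
#' may stem from a PCR error rather than hypermutation), otherwise mutated.
#'
#' @param n_diff Integer vector of nucleotide-difference counts.
#' @param policy A [clone_policy()].
#' @return Character vector, `"mutated"` or `"unmutated"`.
#' @export
classify_mutation_status <- function(n_diff, policy = clone_policy()) {
  policy <- as_clone_policy(policy)
  ifelse(n_diff <= policy$unmutated_max_diff, "unmutated", "mutated")
}

#' Add mutation-profile columns to an annotated rearrangement table
#'
#' For every record with a V assignment, counts nucleotide differences to
#' the assigned germline V gene over the V-gene portion of the alignment
#' (before the 2nd-CYS anchor) and classifies the cell as mutated or
#' unmutated.
#'
#' @param rearr An annotated tibble from [annotate_rearrangements()].
#' @param germlines The `germline_set` used for annotation (for anchors).
#' @param policy A [clone_policy()].
#' @param leading_trim Leading germline positions excluded from the count
#'   (primer-binding stretch); default 0.
#' @return `rearr` with columns `v_mutation_count`, `v_aligned_length`,
#'   `v_mutation_freq_pct` (percent, unrounded), `v_mutation_positions` and
#'   `mutation_status` added.
#' @export
profile_mutations <- function(rearr, germlines, policy = clone_policy(),
                              leading_trim = 0L) {
  policy <- as_clone_policy(policy)
  anchors <- germlines$anchor[match(rearr$v_call, germlines$name)]
  prof <- purrr::map2(seq_len(nrow(rearr)), anchors, function(i, anc) {
    row <- rearr[i, ]
    if (is.na(row$v_call)) return(NULL)
    tryCatch(
      count_v_mutations(
        tibble::tibble(germ_aligned = row$v_germ_aligned,
                       query_aligned = row$v_query_aligned,
                       g_start = row$v_germ_start, q_start = row$v_seq_start),
        v_anchor_germ = anc, leading_trim = leading_trim),
      error = function(e) NULL)
  })
  empty <- tibble::tibble(n_diff = NA_integer_, aligned_len = NA_integer_,
                          freq_pct = NA_real_, positions = NA_character_)
  prof <- dplyr::bind_rows(lapply(prof, function(p) p %||% empty))
  rearr$v_mutation_count <- prof$n_diff
  rearr$v_aligned_length <- prof$aligned_len
  rearr$v_mutation_freq_pct <- prof$freq_pct
  rearr$v_mutation_positions <- prof$positions
  rearr$mutation_status <- ifelse(
    is.na(prof$n_diff), NA_character_,
    classify_mutation_status(prof$n_diff, policy))
  rearr
}

#' Summarise mutation status over one sample
#'
#' @param status Character vector of `"mutated"`/`"unmutated"` calls
#'   (`NA` dropped).
#' @param freq_pct Mutation frequencies (percent) aligned with `status`.
#' @return A one-row tibble: `n`, `pct_mutated` (1 decimal),
#'   `mean_freq_of_mutated` (1 decimal; `NA` when no cell is mutated).
#' @export
sample_mutation_summary <- function(status, freq_pct) {
  keep <- !is.na(status)
  status <- status[keep]
  freq_pct <- freq_pct[keep]
  if (length(status) == 0L) stop("no mutation profiles to summarise",
                                 call. = FALSE)
  mut <- status == "mutated"
  tibble::tibble(
    n = length(status),
    pct_mutated = round(mean(mut) * 100, 1),
    mean_freq_of_mutated = if (any(mut)) round(mean(freq_pct[mut]), 1)
                           else NA_real_
  )
}
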