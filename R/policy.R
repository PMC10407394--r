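#' Clone-calling and mutation-calling rule parameters
#'
#' Bundles the four numeric rule constants used throughout the pipeline in
#' one validated object: the minimum exact run length required to assign an
#' IGHD gene, the maximum number of nucleotide differences a V gene may carry
#' and still be called unmutated, the maximum relative CDR3 length difference
#' between co-clonal cells, and the minimum pairwise CDR3 nucleotide identity
#' (strict: a pair at exactly the threshold is *not* co-clonal).
#'
#' @param d_min_run Minimum length (nt) of an exact common substring between
#'   the CDR3 and a germline IGHD gene for a D call. Default 7.
#' @param unmutated_max_diff Maximum number of nucleotide differences to the
#'   germline V gene for a cell to be classified unmutated. Default 1 (a
#'   single difference may be a PCR artifact rather than hypermutation).
#' @param cdr3_max_len_diff_pct Maximum CDR3 length difference, as a percent
#'   of the longer CDR3, for two cells to be co-clonal (inclusive). Default 5.
#' @param cdr3_min_identity_pct Minimum pairwise CDR3 nucleotide identity
#'   (percent, exclusive: identity must exceed this) for two cells to be
#'   co-clonal. Default 90.
#'
#' @return An object of class `clone_policy` (a named list).
#' @examples
#' clone_policy()
#' clone_policy(cdr3_min_identity_pct = 95)
#' @export
clone_policy <- function(d_min_run = 7L,
                         unmutated_max_diff = 1L,
                         cdr3_max_len_diff_pct = 5,
                         cdr3_min_identity_pct = 90) {
  d_min_run <- as.integer(d_min_run)
  unmutated_max_diff <- as.integer(unmutated_max_diff)
  stopifnot(
    length(d_min_run) == 1L, d_min_run >= 0L,
    length(unmutated_max_diff) == 1L, unmutated_max_diff >= 0L,
    length(cdr3_max_len_diff_pct) == 1L, cdr3_max_len_diff_pct >= 0,
    length(cdr3_min_identity_pct) == 1L,
    cdr3_min_identity_pct > 0, cdr3_min_identity_pct <= 100
  )
  structure(
    list(
      d_min_run = d_min_run,
      unmutated_max_diff = unmutated_max_diff,
      cdr3_max_len_diff_pct = cdr3_max_len_diff_pct,
      cdr3_min_identity_pct = cdr3_min_identity_pct
    ),
    class = "clone_policy"
  )
}

#' @export
print.clone_policy <- function(x, ...) {
  cat("<clone_policy>\n")
  cat("  D gene: exact run of >=", x$d_min_run, "nt required\n")
  cat("  unmutated: <=", x$unmutated_max_diff, "nt difference to germline V\n")
  cat("  co-clonal: CDR3 length diff <=", x$cdr3_max_len_diff_pct,
      "% and CDR3 identity >", x$cdr3_min_identity_pct, "%\n")
  invisible(x)
}

as_clone_policy <- function(x) {
  if (inherits(x, "clone_policy")) return(x)
  if (is.list(x)) return(do.call(clone_policy, x))
  stop("`policy` must be a clone_policy object", call. = FALSE)
}
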