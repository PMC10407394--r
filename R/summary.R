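#' Per-sample summary of the single-cell IGHV analysis
#'
#' Builds one row per sample in the shape of a per-case repertoire summary
#' table: number of cells with an IGHV amplificate, fraction of cells with
#' mutated V genes, mean mutation frequency of the mutated cells, the
#' inventory of expanded (>=2-member) clones split by mutation status, the
#' number of expanded clones with intraclonal diversity, and V-gene usage
#' over productive rearrangements.
#'
#' @param rearr A clone-called tibble from [call_clones()].
#' @return A tibble with one row per `sample_id`: `n_cells_with_ighv`,
#'   `pct_mutated`, `mean_freq_of_mutated` (both 1 decimal),
#'   `clones_unmutated`, `clones_mutated` (inventory strings such as
#'   `"2x 2 cells,1x 3 cells"`, `"0"` when none), `n_clones_expanded`,
#'   `n_clones_mutated`, `n_clones_unmutated`, `n_clones_with_diversity`,
#'   and `v_gene_usage` (list-column of per-gene counts over productive
#'   records).
#' @export
summarize_samples <- function(rearr) {
  stopifnot(is.data.frame(rearr), nrow(rearr) > 0L)
  clones <- summarize_clones(rearr)
  purrr::map_dfr(unique(rearr$sample_id), function(s) {
    rs <- rearr[rearr$sample_id == s, ]
    cs <- clones[clones$sample_id == s & clones$clone_size >= 2L, ]
    ms <- sample_mutation_summary(rs$mutation_status, rs$v_mutation_freq_pct)
    usage <- rs |>
      dplyr::filter(!is.na(.data$productive), .data$productive,
                    !is.na(.data$v_gene)) |>
      dplyr::count(.data$v_gene, name = "n_productive") |>
      dplyr::arrange(dplyr::desc(.data$n_productive), .data$v_gene)
    tibble::tibble(
      sample_id = s,
      n_cells_with_ighv = nrow(rs),
      pct_mutated = ms$pct_mutated,
      mean_freq_of_mutated = ms$mean_freq_of_mutated,
      clones_unmutated = clone_inventory_string(
        cs$clone_size[cs$clone_status == "unmutated"]),
      clones_mutated = clone_inventory_string(
        cs$clone_size[cs$clone_status == "mutated"]),
      n_clones_expanded = nrow(cs),
      n_clones_mutated = sum(cs$clone_status == "mutated"),
      n_clones_unmutated = sum(cs$clone_status == "unmutated"),
      n_clones_with_diversity = sum(cs$intraclonal_diversity),
      v_gene_usage = list(usage)
    )
  })
}

# "2x 2 cells,1x 3 cells" (ascending clone size); "0" when empty
clone_inventory_string <- function(sizes) {
  sizes <- sizes[!is.na(sizes)]
  if (length(sizes) == 0L) return("0")
  tab <- table(sizes)
  paste(paste0(as.integer(tab), "x ", names(tab), " cells"), collapse = ",")
}

#' Render per-sample summaries as a plain-text table
#'
#' @param summaries A tibble from [summarize_samples()].
#' @return A character vector of lines (tab-separated, header first),
#'   printed to the console when the result is not assigned.
#' @export
render_summary_table <- function(summaries) {
  stopifnot(nrow(summaries) >= 1L)
  header <- paste("Sample", "No. of cells with IGHV amplificates",
                  "Fraction of cells with mutated IGHV genes (%)",
                  "Average mutation frequency of mutated IGHV genes (%)",
                  "Unmutated clones", "Mutated clones",
                  "Clones with intraclonal diversity",
                  sep = "\t")
  rows <- purrr::pmap_chr(
    list(summaries$sample_id, summaries$n_cells_with_ighv,
         summaries$pct_mutated, summaries$mean_freq_of_mutated,
         summaries$clones_unmutated, summaries$clones_mutated,
         summaries$n_clones_with_diversity),
    function(s, n, pm, mf, cu, cm, nd) {
      paste(s, n, format_1dp(pm), ifelse(is.na(mf), "-", format_1dp(mf)),
            cu, cm, nd, sep = "\t")
    })
  structure(c(header, rows), class = "summary_table")
}

format_1dp <- function(x) formatC(x, format = "f", digits = 1)

#' @export
print.summary_table <- function(x, ...) {
  cat(paste(unclass(x), collapse = "\n"), "\n")
  invisible(x)
}
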