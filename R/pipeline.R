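#' Read single-cell sequences from FASTA
#'
#' @param path FASTA path (one record per microdissected cell).
#' @param manifest Optional path to a TSV mapping `sequence_id` to
#'   `sample_id` (or a data frame with those columns). Records absent from
#'   the manifest keep sample `"S1"`.
#' @return A tibble: `sequence_id`, `sample_id`, `sequence`.
#' @export
read_cell_fasta <- function(path, manifest = NULL) {
  fa <- Biostrings::readBStringSet(path)
  if (length(fa) == 0L) stop("no input records in ", path, call. = FALSE)
  ids <- purrr::map_chr(names(fa), ~ stringr::str_split_1(.x, "\\s+")[1])
  cells <- tibble::tibble(
    sequence_id = ids,
    sample_id = "S1",
    sequence = toupper(unname(as.character(fa)))
  )
  if (!is.null(manifest)) {
    man <- if (is.data.frame(manifest)) tibble::as_tibble(manifest) else
      readr::read_tsv(manifest, col_types = readr::cols(.default = "c"))
    stopifnot(all(c("sequence_id", "sample_id") %in% names(man)))
    idx <- match(cells$sequence_id, man$sequence_id)
    cells$sample_id[!is.na(idx)] <- man$sample_id[idx[!is.na(idx)]]
  }
  cells
}

#' Run the full single-cell IGHV analysis pipeline
#'
#' Executes load, annotate (V/D/J assignment, junction extraction,
#' productivity), mutation profiling, clone calling and per-sample
#' summarisation, optionally writing the rearrangement TSV, the per-sample
#' summary TSV and a plain-text report to an output directory. Output files
#' carry the germline provenance string and the full policy values in `#`
#' header comments, and contain no timestamps, so reruns on identical
#' inputs are byte-identical.
#'
#' @param cells Input cells: a FASTA path or a data frame with
#'   `sequence_id`, `sequence` (and optionally `sample_id`).
#' @param germlines A merged `germline_set`, or a named list of FASTA paths
#'   `list(v = , d = , j = )` (optionally `v_anchors`/`j_anchors` sidecar
#'   TSV paths).
#' @param manifest Optional manifest (see [read_cell_fasta()]); ignored
#'   when `cells` already carries `sample_id`.
#' @param policy A [clone_policy()].
#' @param productive_only Restrict clone calling to productive records.
#' @param leading_trim Leading germline V positions excluded from mutation
#'   counts (primer-binding stretch); default 0.
#' @param min_v_score,min_j_score Alignment score thresholds.
#' @param out_dir Optional output directory; created if missing.
#' @return A list: `rearrangements` (annotated, profiled, clone-called
#'   tibble), `summary` (per-sample tibble), `report` (text table lines),
#'   `log` (stage-by-stage record counts).
#' @examples
#' ref <- synthetic_germline_set(seed = 11)
#' sim <- simulate_repertoire(sim_config(n_cells = 8, seed = 11), ref)
#' res <- run_pipeline(sim$cells, ref)
#' res$summary
#' @export
run_pipeline <- function(cells, germlines, manifest = NULL,
                         policy = clone_policy(), productive_only = TRUE,
                         leading_trim = 0L,
                         min_v_score = 40, min_j_score = 15,
                         out_dir = NULL) {
  policy <- as_clone_policy(policy)
  if (is.character(cells)) cells <- read_cell_fasta(cells, manifest)
  if (is.list(germlines) && !is.data.frame(germlines)) {
    germlines <- merge_germline_sets(
      read_germline_fasta(germlines$v, "V", anchors = germlines$v_anchors),
      read_germline_fasta(germlines$d, "D"),
      read_germline_fasta(germlines$j, "J", anchors = germlines$j_anchors)
    )
  }
  log <- character()
  note <- function(...) log <<- c(log, paste0(...))
  note("records in: ", nrow(cells))

  rearr <- annotate_rearrangements(cells, germlines, policy,
                                   min_v_score = min_v_score,
                                   min_j_score = min_j_score)
  note("V assigned: ", sum(!is.na(rearr$v_call)))
  note("CDR3 resolved: ", sum(!is.na(rearr$cdr3)))
  note("productive: ", sum(rearr$productive, na.rm = TRUE))

  rearr <- profile_mutations(rearr, germlines, policy,
                             leading_trim = leading_trim)
  note("mutation-profiled: ", sum(!is.na(rearr$mutation_status)))

  rearr <- call_clones(rearr, policy, productive_only = productive_only)
  n_expanded <- rearr |>
    dplyr::filter(!.data$clone_unclustered) |>
    dplyr::distinct(.data$clone_id, .data$clone_size) |>
    dplyr::filter(.data$clone_size >= 2L) |>
    nrow()
  note("expanded clones (>=2 members): ", n_expanded)

  summary <- summarize_samples(rearr)
  report <- render_summary_table(summary)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_rearrangement_tsv(
      rearr, file.path(out_dir, "rearrangements.tsv"), policy,
      provenance = attr(germlines, "provenance"))
    write_summary_tsv(
      summary, file.path(out_dir, "sample_summary.tsv"), policy,
      provenance = attr(germlines, "provenance"))
    writeLines(unclass(report), file.path(out_dir, "report.txt"))
  }
  list(rearrangements = rearr, summary = summary, report = report, log = log)
}

tsv_header_comments <- function(policy, provenance) {
  c(paste0("# germline_provenance: ", provenance %||% "unknown"),
    paste0("# policy: d_min_run=", policy$d_min_run,
           " unmutated_max_diff=", policy$unmutated_max_diff,
           " cdr3_max_len_diff_pct=", policy$cdr3_max_len_diff_pct,
           " cdr3_min_identity_pct=", policy$cdr3_min_identity_pct))
}

REARR_TSV_COLUMNS <- c(
  "sequence_id", "sample_id", "v_call", "v_gene", "d_call", "j_call",
  "junction", "cdr3", "junction_length", "productive", "productivity",
  "v_identity", "v_score",
  "v_mutation_count", "v_aligned_length", "v_mutation_freq_pct",
  "v_mutation_positions", "mutation_status",
  "clone_id", "clone_size", "clone_status", "intraclonal_diversity",
  "n_variants", "sequence"
)

#' Write the AIRR-style rearrangement table to TSV
#'
#' @param rearr Clone-called tibble.
#' @param path Output path.
#' @param policy,provenance Recorded in `#` header comments.
#' @return `path`, invisibly.
#' @export
write_rearrangement_tsv <- function(rearr, path, policy = clone_policy(),
                                    provenance = NULL) {
  out <- rearr[, intersect(REARR_TSV_COLUMNS, names(rearr))]
  out$v_mutation_freq_pct <- round(out$v_mutation_freq_pct, 4)
  out$v_identity <- round(out$v_identity, 3)
  writeLines(tsv_header_comments(as_clone_policy(policy), provenance), path)
  readr::write_tsv(out, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Write the per-sample summary table to TSV
#'
#' @inheritParams write_rearrangement_tsv
#' @param summary Per-sample tibble from [summarize_samples()].
#' @export
write_summary_tsv <- function(summary, path, policy = clone_policy(),
                              provenance = NULL) {
  flat <- summary |>
    dplyr::mutate(v_gene_usage = purrr::map_chr(
      .data$v_gene_usage,
      ~ paste(paste0(.x$v_gene, ":", .x$n_productive), collapse = ",")))
  writeLines(tsv_header_comments(as_clone_policy(policy), provenance), path)
  readr::write_tsv(flat, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Read back a rearrangement TSV written by the pipeline
#'
#' @param path TSV path (header comments are skipped).
#' @return A tibble.
#' @export
read_rearrangement_tsv <- function(path) {
  readr::read_tsv(path, comment = "#", col_types = readr::cols(
    sequence_id = "c", sample_id = "c", v_call = "c", v_gene = "c",
    d_call = "c", j_call = "c", junction = "c", cdr3 = "c",
    productive = "l", productivity = "c", v_mutation_positions = "c",
    mutation_status = "c", clone_id = "c", clone_status = "c",
    sequence = "c", .default = readr::col_guess()
  ))
}
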