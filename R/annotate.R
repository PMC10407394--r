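#' Assign the germline V gene to a rearranged sequence
#'
#' Scores the query against every germline V gene by local alignment under
#' the pipeline's fixed scheme (match +1, mismatch -1, gap open -4, gap
#' extend -1/base) and returns the best hit. Ties are broken by higher
#' identity, longer aligned span, then smallest gene name, so the result is
#' deterministic.
#'
#' @param sequence A DNA string (the rearranged V region, FR1-primed).
#' @param germlines A `germline_set` containing V genes.
#' @param min_score Minimum alignment score for a call (default 40).
#' @return A one-row tibble (gene, score, identity_pct, spans, mismatch and
#'   indel counts, plus the aligned strings used downstream).
#' @export
assign_v_gene <- function(sequence, germlines, min_score = 40) {
  vset <- germlines[germlines$segment_class == "V", ]
  if (nrow(vset) == 0L) stop("no V genes in germline set", call. = FALSE)
  best <- assign_segment_batch(toupper(sequence), vset$sequence, vset$name)
  if (best$score < min_score) {
    stop("no V assignment (best score ", best$score, " for ", best$gene,
         ", below ", min_score, ")", call. = FALSE)
  }
  best
}

#' Assign the germline J gene downstream of the V alignment
#'
#' Searches the query region to the right of the V alignment end (minus a
#' 10-nt overlap allowance) for the best local J-gene alignment under the
#' same scheme and tie-breaking as [assign_v_gene()]. The J span must not
#' start left of the V 2nd-CYS anchor image on the query.
#'
#' @param sequence The full query DNA string.
#' @param germlines A `germline_set` containing J genes.
#' @param v A one-row V assignment tibble from [assign_v_gene()].
#' @param v_anchor_q Optional 0-based query position of the V 2nd-CYS codon
#'   (used as a left bound for the J span when available).
#' @param min_score Minimum alignment score for a call (default 15).
#' @return A one-row tibble with query spans on the full sequence.
#' @export
assign_j_gene <- function(sequence, germlines, v, v_anchor_q = NA_integer_,
                          min_score = 15) {
  jset <- germlines[germlines$segment_class == "J", ]
  if (nrow(jset) == 0L) stop("no J genes in germline set", call. = FALSE)
  sequence <- toupper(sequence)
  offset <- j_search_offset(v$q_end, v_anchor_q)
  region <- substr(sequence, offset + 1L, nchar(sequence))
  if (nchar(region) < 10L) {
    stop("no J assignment (no sequence right of the V gene)", call. = FALSE)
  }
  best <- assign_segment_batch(region, jset$sequence, jset$name)
  if (best$score < min_score) {
    stop("no J assignment (best score ", best$score, " for ", best$gene,
         ", below ", min_score, ")", call. = FALSE)
  }
  best$q_start <- best$q_start + offset
  best$q_end <- best$q_end + offset
  best
}

j_search_offset <- function(v_q_end, v_anchor_q) {
  offset <- max(0L, v_q_end - 10L)
  if (!is.na(v_anchor_q)) offset <- max(offset, v_anchor_q)
  as.integer(offset)
}

#' Extract the junction and CDR3 from assigned V and J alignments
#'
#' Maps the V-gene 2nd-CYS anchor and the J-gene J-TRP/J-PHE anchor through
#' their alignments onto the query. The junction runs from the first base of
#' the 2nd-CYS codon through the last base of the J anchor codon; the CDR3
#' is the junction minus the two anchor codons.
#'
#' @param sequence Query DNA string.
#' @param v,j One-row assignment tibbles from [assign_v_gene()] /
#'   [assign_j_gene()].
#' @param germlines The `germline_set` holding both genes (for anchors).
#' @return A one-row tibble: `junction`, `cdr3`, `junction_length`,
#'   `frame_offset` (junction length mod 3), `contains_stop` (stop codon in
#'   the translated in-frame junction), and the anchor images
#'   `v_anchor_q`, `j_anchor_q` (0-based query positions).
#'   Returns `NULL` (junction unresolved) when an anchor is missing, falls
#'   outside its aligned span, maps onto a gap, or the junction is shorter
#'   than 9 nt.
#' @export
extract_junction <- function(sequence, v, j, germlines) {
  sequence <- toupper(sequence)
  v_gene <- germlines[germlines$name == v$gene, ]
  j_gene <- germlines[germlines$name == j$gene, ]
  if (nrow(v_gene) != 1L || nrow(j_gene) != 1L) return(NULL)
  if (is.na(v_gene$anchor) || is.na(j_gene$anchor)) return(NULL)

  v_anchor_q <- map_germline_to_query(v, v_gene$anchor)
  j_anchor_q <- map_germline_to_query(j, j_gene$anchor)
  if (is.na(v_anchor_q) || is.na(j_anchor_q)) return(NULL)
  if (j_anchor_q + 3L > nchar(sequence)) return(NULL)
  junction <- substr(sequence, v_anchor_q + 1L, j_anchor_q + 3L)
  if (nchar(junction) < 9L) return(NULL)
  cdr3 <- substr(junction, 4L, nchar(junction) - 3L)
  frame_offset <- nchar(junction) %% 3L
  contains_stop <- if (frame_offset == 0L) has_stop(junction) else NA
  tibble::tibble(
    junction = junction,
    cdr3 = cdr3,
    junction_length = nchar(junction),
    frame_offset = frame_offset,
    contains_stop = contains_stop,
    v_anchor_q = v_anchor_q,
    j_anchor_q = j_anchor_q
  )
}

#' Assign the IGHD gene by the exact-run rule
#'
#' A D gene is assigned only if at least `policy$d_min_run` consecutive
#' bases of the CDR3 exactly match the candidate germline D sequence
#' (forward orientation, no reading-frame requirement). Among qualifying
#' genes the longest run wins; ties go to the smallest gene name. Absence of
#' a D call is a legitimate outcome, not an error.
#'
#' @param cdr3_nt CDR3 nucleotide string.
#' @param germlines A `germline_set` containing D genes.
#' @param policy A [clone_policy()].
#' @return A one-row tibble (`gene`, `run_length`, `identity_pct` = 100) or
#'   `NULL` when no gene reaches the minimum run.
#' @export
assign_d_gene <- function(cdr3_nt, germlines, policy = clone_policy()) {
  policy <- as_clone_policy(policy)
  dset <- germlines[germlines$segment_class == "D", ]
  if (nrow(dset) == 0L || is.na(cdr3_nt) || nchar(cdr3_nt) == 0L) return(NULL)
  cdr3_nt <- toupper(cdr3_nt)
  runs <- vapply(dset$sequence, function(d) {
    longest_common_substring(cdr3_nt, d)
  }, integer(1))
  best_run <- max(runs)
  if (best_run < policy$d_min_run) return(NULL)
  cand <- dset$name[runs == best_run]
  tibble::tibble(
    gene = sort(cand)[1],
    run_length = as.integer(best_run),
    identity_pct = 100
  )
}

# Longest exact common substring length between two DNA strings, by dynamic
# programming over suffix-run lengths (one row kept).
longest_common_substring <- function(a, b) {
  na <- nchar(a); nb <- nchar(b)
  if (na == 0L || nb == 0L) return(0L)
  av <- utf8ToInt(a); bv <- utf8ToInt(b)
  best <- 0L
  prev <- integer(nb)
  for (i in seq_len(na)) {
    cur <- integer(nb)
    hit <- which(bv == av[i])
    if (length(hit) > 0L) {
      cur[hit] <- 1L
      inner <- hit[hit > 1L]
      if (length(inner) > 0L) cur[inner] <- prev[inner - 1L] + 1L
      m <- max(cur)
      if (m > best) best <- m
    }
    prev <- cur
  }
  best
}

#' Classify the productivity of an annotated rearrangement
#'
#' Productive: junction resolved, in frame (junction length divisible by 3),
#' no stop codon in the translated junction, and no stop codon in the V
#' reading frame across the aligned query (from the frame anchored at the
#' 2nd-CYS codon through the end of the J alignment). Nonproductive:
#' junction resolved but out of frame or containing a stop. Unresolved:
#' junction could not be extracted.
#'
#' @param sequence Query DNA string.
#' @param junction_row One-row tibble from [extract_junction()], or `NULL`.
#' @param j_q_end 0-based half-open end of the J alignment on the query.
#' @return `"productive"`, `"nonproductive"` or `"unresolved"`.
#' @export
classify_productivity <- function(sequence, junction_row, j_q_end = NULL) {
  if (is.null(junction_row) || nrow(junction_row) == 0L) return("unresolved")
  if (junction_row$frame_offset != 0L) return("nonproductive")
  if (isTRUE(junction_row$contains_stop)) return("nonproductive")
  sequence <- toupper(sequence)
  frame_start <- junction_row$v_anchor_q %% 3L
  stop_at <- nchar(sequence)
  if (!is.null(j_q_end)) stop_at <- min(stop_at, as.integer(j_q_end))
  orf <- substr(sequence, frame_start + 1L, stop_at)
  if (has_stop(orf)) return("nonproductive")
  "productive"
}

#' Annotate a table of single-cell IGH sequences
#'
#' The per-cell annotation stage: for each record, assigns the germline V
#' and J genes by local alignment, extracts the junction/CDR3, assigns the
#' D gene by the exact-run rule, and classifies productivity. Records that
#' fail V or J assignment or junction extraction are retained with `NA`
#' calls and `productive = NA` (status `"unresolved"`). V and J alignments
#' are batched across cells (one alignment call per germline gene), so
#' whole samples annotate quickly.
#'
#' @param cells A data frame with columns `sequence_id` and `sequence`
#'   (optionally `sample_id`; missing sample labels become `"S1"`).
#' @param germlines A merged `germline_set` with V, D and J genes.
#' @param policy A [clone_policy()].
#' @param min_v_score,min_j_score Alignment score thresholds.
#' @return An AIRR-style tibble with one row per input record: `sequence_id`,
#'   `sample_id`, `sequence`, `v_call`, `v_gene`, `d_call`, `j_call`,
#'   `junction`, `cdr3`, `junction_length`, `productive` (logical; `NA` when
#'   unresolved), `productivity`, `v_identity`, `v_score`, alignment spans,
#'   and internal anchor columns used by downstream stages.
#' @examples
#' ref <- synthetic_germline_set(seed = 7)
#' sim <- simulate_repertoire(sim_config(n_cells = 5, seed = 7), ref)
#' annotate_rearrangements(sim$cells, ref)
#' @export
annotate_rearrangements <- function(cells, germlines,
                                    policy = clone_policy(),
                                    min_v_score = 40, min_j_score = 15) {
  stopifnot(is.data.frame(cells),
            all(c("sequence_id", "sequence") %in% names(cells)))
  if (nrow(cells) == 0L) stop("no input records", call. = FALSE)
  policy <- as_clone_policy(policy)
  cells <- tibble::as_tibble(cells)
  if (!"sample_id" %in% names(cells)) cells$sample_id <- "S1"
  cells$sample_id[is.na(cells$sample_id)] <- "S1"
  n <- nrow(cells)
  seqs <- toupper(cells$sequence)

  vset <- germlines[germlines$segment_class == "V", ]
  jset <- germlines[germlines$segment_class == "J", ]
  if (nrow(vset) == 0L) stop("no V genes in germline set", call. = FALSE)
  if (nrow(jset) == 0L) stop("no J genes in germline set", call. = FALSE)

  out <- tibble::tibble(
    sequence_id = cells$sequence_id, sample_id = cells$sample_id,
    sequence = seqs,
    v_call = NA_character_, v_gene = NA_character_,
    d_call = NA_character_, j_call = NA_character_,
    junction = NA_character_, cdr3 = NA_character_,
    junction_length = NA_integer_,
    productive = NA, productivity = "unresolved",
    v_identity = NA_real_, v_score = NA_real_,
    v_seq_start = NA_integer_, v_seq_end = NA_integer_,
    v_germ_start = NA_integer_, v_germ_end = NA_integer_,
    j_seq_start = NA_integer_, j_seq_end = NA_integer_,
    j_germ_start = NA_integer_,
    v_anchor_q = NA_integer_,
    v_germ_aligned = NA_character_, v_query_aligned = NA_character_,
    annotation_note = NA_character_
  )

  v_best <- assign_segment_batch(seqs, vset$sequence, vset$name)
  v_ok <- v_best$score >= min_v_score
  out$annotation_note[!v_ok] <- paste0(
    "no V assignment (best score ", v_best$score[!v_ok], " for ",
    v_best$gene[!v_ok], ", below ", min_v_score, ")")
  out$v_call[v_ok] <- v_best$gene[v_ok]
  out$v_gene[v_ok] <- strip_allele(v_best$gene[v_ok])
  out$v_identity[v_ok] <- round(v_best$identity_pct[v_ok], 3)
  out$v_score[v_ok] <- v_best$score[v_ok]
  out$v_seq_start[v_ok] <- v_best$q_start[v_ok]
  out$v_seq_end[v_ok] <- v_best$q_end[v_ok]
  out$v_germ_start[v_ok] <- v_best$g_start[v_ok]
  out$v_germ_end[v_ok] <- v_best$g_end[v_ok]
  out$v_germ_aligned[v_ok] <- v_best$germ_aligned[v_ok]
  out$v_query_aligned[v_ok] <- v_best$query_aligned[v_ok]

  v_anchor <- vset$anchor[match(out$v_call, vset$name)]
  out$v_anchor_q[v_ok] <- vapply(which(v_ok), function(i) {
    if (is.na(v_anchor[i])) return(NA_integer_)
    map_germline_to_query(v_best[i, ], v_anchor[i])
  }, integer(1))

  # J search regions (right of V end / 2nd-CYS image), batched per J gene
  offsets <- vapply(seq_len(n), function(i) {
    if (!v_ok[i]) return(NA_integer_)
    j_search_offset(out$v_seq_end[i], out$v_anchor_q[i])
  }, integer(1))
  regions <- ifelse(is.na(offsets), NA_character_,
                    substr(seqs, offsets + 1L, nchar(seqs)))
  j_idx <- which(v_ok & !is.na(regions) & nchar(regions) >= 10L)
  out$annotation_note[v_ok & !(seq_len(n) %in% j_idx)] <-
    "no J assignment (no sequence right of the V gene)"
  if (length(j_idx) > 0L) {
    j_best <- assign_segment_batch(regions[j_idx], jset$sequence, jset$name)
    j_ok <- j_best$score >= min_j_score
    bad <- j_idx[!j_ok]
    out$annotation_note[bad] <- paste0(
      "no J assignment (best score ", j_best$score[!j_ok], " for ",
      j_best$gene[!j_ok], ", below ", min_j_score, ")")
    good <- j_idx[j_ok]
    jb <- j_best[j_ok, , drop = FALSE]
    out$j_call[good] <- jb$gene
    out$j_seq_start[good] <- jb$q_start + offsets[good]
    out$j_seq_end[good] <- jb$q_end + offsets[good]
    out$j_germ_start[good] <- jb$g_start

    for (k in seq_along(good)) {
      i <- good[k]
      v_row <- v_best[i, ]
      j_row <- jb[k, , drop = FALSE]
      j_row$q_start <- out$j_seq_start[i]
      j_row$q_end <- out$j_seq_end[i]
      jr <- extract_junction(seqs[i], v_row, j_row, germlines)
      if (is.null(jr)) {
        out$annotation_note[i] <- "junction unresolved"
        next
      }
      out$junction[i] <- jr$junction
      out$cdr3[i] <- jr$cdr3
      out$junction_length[i] <- jr$junction_length
      d <- assign_d_gene(jr$cdr3, germlines, policy)
      if (!is.null(d)) out$d_call[i] <- d$gene
      prod <- classify_productivity(seqs[i], jr, j_q_end = out$j_seq_end[i])
      out$productivity[i] <- prod
      out$productive[i] <- if (prod == "unresolved") NA else
        prod == "productive"
    }
  }
  attr(out, "provenance") <- attr(germlines, "provenance")
  out
}
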