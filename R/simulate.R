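#' Configuration for the synthetic repertoire generator
#'
#' Captures one sample's generating conditions: sample size, the fraction
#' of cells carrying somatic hypermutation (SHM), the per-base SHM rate on
#' the V segment of mutated cells, the clonal structure (a few expanded
#' clones over a mostly-singleton background), and the junctional-diversity
#' parameters of the V(D)J join (exonuclease trimming and non-templated
#' N insertions).
#'
#' @param n_cells Number of cells to emit.
#' @param mutated_fraction Target fraction of cells with SHM (study-range
#'   ~0.45-0.90; default 0.65).
#' @param shm_rate Per-base substitution probability over the mutable V
#'   span of mutated cells (study-range ~0.03-0.09; default 0.06).
#' @param clone_spec Data frame with columns `size` (members, >= 1),
#'   `mutated` (logical) and `extra_mut` (Poisson mean of additional
#'   per-member branch mutations; > 0 yields intraclonal diversity).
#'   Default: two diversifying mutated clones (sizes 2 and 3) and one
#'   unmutated clone of 2.
#' @param trim_max Maximum exonuclease trim (nt) at each of 3'V, 5'D, 3'D,
#'   5'J (default 6).
#' @param n_insert_max Maximum N-nucleotide insertion per junction side
#'   (default 8).
#' @param productive_only Resample junction arithmetic until each
#'   rearrangement is in frame and stop-free (default `TRUE`).
#' @param shm_protect_5p Leading germline V positions never mutated
#'   (the FR1 primer-binding stretch is primer-templated in an amplicon;
#'   default 18).
#' @param min_event_divergence_pct Minimum CDR3 divergence (percent)
#'   enforced between distinct recombination events, so distinct precursors
#'   are unambiguously distinct (default 20).
#' @param seed Integer seed; the emitted repertoire is fully determined by
#'   it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cells = 30L,
                       mutated_fraction = 0.65,
                       shm_rate = 0.06,
                       clone_spec = default_clone_spec(),
                       trim_max = 6L,
                       n_insert_max = 8L,
                       productive_only = TRUE,
                       shm_protect_5p = 18L,
                       min_event_divergence_pct = 20,
                       seed = 1L) {
  clone_spec <- tibble::as_tibble(clone_spec)
  if (nrow(clone_spec) > 0L) {
    stopifnot(all(c("size", "mutated", "extra_mut") %in% names(clone_spec)),
              all(clone_spec$size >= 1L))
  }
  stopifnot(
    n_cells >= 1L,
    mutated_fraction >= 0, mutated_fraction <= 1,
    shm_rate >= 0, shm_rate <= 0.5,
    trim_max >= 0L, n_insert_max >= 0L,
    sum(clone_spec$size) <= n_cells
  )
  structure(
    list(n_cells = as.integer(n_cells),
         mutated_fraction = mutated_fraction,
         shm_rate = shm_rate,
         clone_spec = clone_spec,
         trim_max = as.integer(trim_max),
         n_insert_max = as.integer(n_insert_max),
         productive_only = isTRUE(productive_only),
         shm_protect_5p = as.integer(shm_protect_5p),
         min_event_divergence_pct = min_event_divergence_pct,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

#' @rdname sim_config
#' @export
default_clone_spec <- function() {
  tibble::tibble(size = c(2L, 3L, 2L),
                 mutated = c(TRUE, TRUE, FALSE),
                 extra_mut = c(1.5, 1.5, 0))
}

#' Simulate one V(D)J rearrangement
#'
#' Draws V, D and J genes uniformly, trims each joining end by an
#' independent uniform amount in `[0, trim_max]`, inserts N-nucleotides of
#' uniform length in `[0, n_insert_max]` and uniform base composition at
#' both joints, and concatenates germline V (full FR1-to-join), the D
#' remnant and the J remnant. With `productive_only` the junction
#' arithmetic (trims and insertions) is resampled up to 100 times until the
#' junction is in frame and the read stop-free.
#'
#' Uses the current RNG stream; seed upstream (e.g. via
#' [simulate_repertoire()]) for reproducibility.
#'
#' @param config A [sim_config()].
#' @param germlines A `germline_set` with anchored V and J genes and D
#'   genes.
#' @param genes Optional named list (`v`, `d`, `j`) fixing the gene draw.
#' @return A list: `sequence` and `truth` (one-row tibble with the
#'   generating gene names, junction/CDR3, anchors on the query, the V-end
#'   position, frame and productivity of the junction arithmetic).
#' @export
simulate_rearrangement <- function(config, germlines, genes = NULL) {
  vset <- germlines[germlines$segment_class == "V" & !is.na(germlines$anchor), ]
  dset <- germlines[germlines$segment_class == "D", ]
  jset <- germlines[germlines$segment_class == "J" & !is.na(germlines$anchor), ]
  stopifnot(nrow(vset) > 0L, nrow(dset) > 0L, nrow(jset) > 0L)

  v <- if (!is.null(genes)) vset[vset$name == genes$v, ] else
    vset[sample.int(nrow(vset), 1L), ]
  d <- if (!is.null(genes)) dset[dset$name == genes$d, ] else
    dset[sample.int(nrow(dset), 1L), ]
  j <- if (!is.null(genes)) jset[jset$name == genes$j, ] else
    jset[sample.int(nrow(jset), 1L), ]
  stopifnot(nrow(v) == 1L, nrow(d) == 1L, nrow(j) == 1L)

  v_len <- nchar(v$sequence)
  d_len <- nchar(d$sequence)
  j_len <- nchar(j$sequence)
  max_tv <- min(config$trim_max, v_len - (v$anchor + 3L))
  max_tj <- min(config$trim_max, j$anchor)

  for (attempt in seq_len(100L)) {
    t_v <- sample.int(max_tv + 1L, 1L) - 1L
    t_j <- sample.int(max_tj + 1L, 1L) - 1L
    t_d5 <- sample.int(min(config$trim_max, d_len) + 1L, 1L) - 1L
    t_d3 <- sample.int(min(config$trim_max, d_len - t_d5) + 1L, 1L) - 1L
    n1 <- sample.int(config$n_insert_max + 1L, 1L) - 1L
    n2 <- sample.int(config$n_insert_max + 1L, 1L) - 1L

    v_part <- substr(v$sequence, 1L, v_len - t_v)
    d_part <- if (d_len - t_d5 - t_d3 > 0L) {
      substr(d$sequence, t_d5 + 1L, d_len - t_d3)
    } else ""
    j_part <- substr(j$sequence, t_j + 1L, j_len)
    n1s <- if (n1 > 0L) random_dna(n1) else ""
    n2s <- if (n2 > 0L) random_dna(n2) else ""
    sequence <- paste0(v_part, n1s, d_part, n2s, j_part)

    v_anchor_q <- v$anchor
    j_anchor_q <- nchar(v_part) + n1 + nchar(d_part) + n2 + (j$anchor - t_j)
    junction <- substr(sequence, v_anchor_q + 1L, j_anchor_q + 3L)
    in_frame <- nchar(junction) %% 3L == 0L
    stop_free <- in_frame && !has_stop(junction)
    if (!config$productive_only || (in_frame && stop_free)) {
      return(list(
        sequence = sequence,
        truth = tibble::tibble(
          v_name = v$name, d_name = d$name, j_name = j$name,
          v_gene = v$gene_name,
          v_end_q = nchar(v_part),
          v_anchor_q = v_anchor_q, j_anchor_q = j_anchor_q,
          junction = junction,
          cdr3 = substr(junction, 4L, nchar(junction) - 3L),
          productive = in_frame && stop_free
        )
      ))
    }
  }
  stop("could not generate a productive junction for ",
       v$name, "/", d$name, "/", j$name, call. = FALSE)
}

#' Implant somatic hypermutation into a sequence
#'
#' Independent per-base Bernoulli(`rate`) substitutions over the given
#' positions; the substituted base is uniform among the three alternatives.
#'
#' @param sequence DNA string.
#' @param positions Integer vector of 0-based positions eligible for
#'   mutation (the mutable V span).
#' @param rate Per-base substitution probability in `[0, 1]`.
#' @return A list: `sequence` (mutated) and `mutations`, a tibble with
#'   columns `pos` (0-based), `ref`, `alt`.
#' @export
apply_shm <- function(sequence, positions, rate) {
  stopifnot(rate >= 0, rate <= 1)
  if (length(positions) == 0L || rate == 0) {
    return(list(sequence = sequence,
                mutations = tibble::tibble(pos = integer(), ref = character(),
                                           alt = character())))
  }
  hit <- positions[stats::runif(length(positions)) < rate]
  mutate_at_positions(sequence, hit)
}

# substitute a uniform alternative base at each given 0-based position
mutate_at_positions <- function(sequence, hit) {
  if (length(hit) == 0L) {
    return(list(sequence = sequence,
                mutations = tibble::tibble(pos = integer(), ref = character(),
                                           alt = character())))
  }
  chars <- stringr::str_split_1(sequence, "")
  ref <- chars[hit + 1L]
  alt <- vapply(ref, function(b) sample(setdiff(BASES, b), 1L), character(1))
  chars[hit + 1L] <- alt
  list(sequence = paste(chars, collapse = ""),
       mutations = tibble::tibble(pos = sort(hit),
                                  ref = ref[order(hit)],
                                  alt = alt[order(hit)]))
}

mutations_string <- function(mut) {
  if (nrow(mut) == 0L) return("")
  paste(paste0(mut$pos, ":", mut$ref, ">", mut$alt), collapse = ";")
}

#' Simulate one clonal expansion
#'
#' One founder rearrangement is drawn (plus founder SHM when the clone is
#' mutated); every member inherits the founder sequence and receives
#' `Poisson(extra_mut)` additional substitutions at so-far-unmutated
#' positions of the mutable V span, so `extra_mut > 0` produces
#' intraclonal diversity. All members share the founder junction exactly.
#'
#' @param size Number of members (>= 1).
#' @param mutated Logical: apply founder SHM at `config$shm_rate`?
#' @param extra_mut Poisson mean of per-member branch mutations.
#' @param config A [sim_config()].
#' @param germlines A `germline_set`.
#' @param founder Optional founder from [simulate_rearrangement()] (used
#'   by [simulate_repertoire()] after divergence screening).
#' @return A list of `size` elements, each a list
#'   (`sequence`, `truth`, `mutations` tibble).
#' @export
simulate_clone <- function(size, mutated, extra_mut, config, germlines,
                           founder = NULL) {
  stopifnot(size >= 1L)
  founder <- founder %||% simulate_rearrangement(config, germlines)
  mutable <- mutable_positions(config, founder)
  # an expanded clone is an *observed* expansion of cells expressing their
  # receptor: when the founder junction is productive, mutation draws that
  # would create a stop codon are redrawn (bounded), for multi-member
  # clones, so configured clone inventories survive annotation
  keep_open <- founder$truth$productive && size >= 2L
  draw_shm <- function(sequence, positions_or_rate, bernoulli) {
    for (i in seq_len(100L)) {
      res <- if (bernoulli) {
        apply_shm(sequence, mutable, positions_or_rate)
      } else {
        n_extra <- if (positions_or_rate > 0) {
          stats::rpois(1L, positions_or_rate)
        } else 0L
        open <- setdiff(mutable, f_shm$mutations$pos)
        hit <- if (n_extra > 0L && length(open) > 0L) {
          sort(sample(open, min(n_extra, length(open))))
        } else integer()
        mutate_at_positions(sequence, hit)
      }
      if (!keep_open || check_productive(res$sequence, founder$truth)) {
        return(res)
      }
    }
    res
  }
  f_shm <- if (mutated) {
    draw_shm(founder$sequence, config$shm_rate, bernoulli = TRUE)
  } else {
    list(sequence = founder$sequence,
         mutations = tibble::tibble(pos = integer(), ref = character(),
                                    alt = character()))
  }
  purrr::map(seq_len(size), function(m) {
    b_shm <- draw_shm(f_shm$sequence, extra_mut, bernoulli = FALSE)
    mut <- dplyr::arrange(dplyr::bind_rows(f_shm$mutations, b_shm$mutations),
                          .data$pos)
    list(sequence = b_shm$sequence, truth = founder$truth, mutations = mut)
  })
}

# 0-based positions of the mutable V span: after the primer-protected FR1
# stretch, before the 2nd-CYS anchor codon (the junction never mutates, so
# clone members share it and truth junctions stay exact)
mutable_positions <- function(config, rearr) {
  lo <- config$shm_protect_5p
  hi <- rearr$truth$v_anchor_q - 1L
  if (hi < lo) return(integer())
  lo:hi
}

#' Simulate a single-cell heavy-chain sample with ground truth
#'
#' Emits `n_cells` sequences: the configured clonal expansions plus
#' singletons, with the configured fraction of cells carrying SHM. Distinct
#' recombination events are redrawn (up to 50 times each) until their
#' CDR3s diverge by more than `min_event_divergence_pct` from every prior
#' event, so the generating partition is unambiguous. Cell identifiers are
#' assigned after shuffling and encode nothing about the truth.
#'
#' @param config A [sim_config()]; `config$seed` fully determines the
#'   output.
#' @param germlines A `germline_set`.
#' @param sample_id Sample label for all emitted cells (default `"S1"`).
#' @return A list of three tibbles:
#'   \describe{
#'     \item{cells}{`sequence_id`, `sample_id`, `sequence` — the blind
#'       input to the pipeline.}
#'     \item{truth}{per cell: generating gene names, `clone_id`
#'       (singletons get unique ids), `n_mutations`, `positions`
#'       (`pos:ref>alt;...`), `junction`, `cdr3`, `productive`,
#'       `mutation_status` under the unmutated-tolerance rule, and
#'       `v_mutation_freq_pct` over the pre-anchor V span.}
#'     \item{truth_summary}{the per-sample summary computed from the truth
#'       table with the same formulas as [summarize_samples()].}
#'   }
#' @examples
#' ref <- synthetic_germline_set(seed = 3)
#' sim <- simulate_repertoire(sim_config(n_cells = 10, seed = 3), ref)
#' sim$truth_summary
#' @export
simulate_repertoire <- function(config, germlines, sample_id = "S1") {
  stopifnot(inherits(config, "sim_config"))
  withr_seed(config$seed)

  spec <- config$clone_spec
  n_clonal <- if (nrow(spec) > 0L) sum(spec$size) else 0L
  n_singletons <- config$n_cells - n_clonal

  # mutated-cell budget: clones contribute their members, singletons fill up
  target_mut <- round(config$n_cells * config$mutated_fraction)
  clone_mut <- if (nrow(spec) > 0L) sum(spec$size[spec$mutated]) else 0L
  n_mut_singletons <- min(n_singletons, max(0L, target_mut - clone_mut))

  accepted_cdr3 <- character()
  accepted_vgene <- character()
  draw_separated_founder <- function() {
    for (i in seq_len(50L)) {
      # a gene triple whose junction arithmetic cannot go productive is
      # simply redrawn here
      cand <- tryCatch(simulate_rearrangement(config, germlines),
                       error = function(e) NULL)
      if (is.null(cand)) next
      if (event_separated(cand$truth$cdr3, cand$truth$v_gene,
                          accepted_cdr3, accepted_vgene,
                          config$min_event_divergence_pct)) {
        accepted_cdr3 <<- c(accepted_cdr3, cand$truth$cdr3)
        accepted_vgene <<- c(accepted_vgene, cand$truth$v_gene)
        return(cand)
      }
    }
    stop("could not draw a sufficiently divergent recombination event",
         call. = FALSE)
  }

  cells <- list()
  add_cell <- function(member, clone_id, shm_flag) {
    cells[[length(cells) + 1L]] <<- list(member = member, clone_id = clone_id,
                                         shm = shm_flag)
  }

  if (nrow(spec) > 0L) {
    for (ci in seq_len(nrow(spec))) {
      founder <- draw_separated_founder()
      members <- simulate_clone(spec$size[ci], spec$mutated[ci],
                                spec$extra_mut[ci], config, germlines,
                                founder = founder)
      for (m in members) add_cell(m, paste0("clone", ci), spec$mutated[ci])
    }
  }
  if (n_singletons > 0L) {
    mut_flags <- rep(FALSE, n_singletons)
    if (n_mut_singletons > 0L) {
      mut_flags[sample.int(n_singletons, n_mut_singletons)] <- TRUE
    }
    for (si in seq_len(n_singletons)) {
      founder <- draw_separated_founder()
      member <- simulate_clone(1L, mut_flags[si], 0, config, germlines,
                               founder = founder)[[1L]]
      add_cell(member, paste0("singleton", si), mut_flags[si])
    }
  }

  ord <- sample.int(length(cells))
  ids <- sprintf("cell_%03d", seq_along(cells))
  rows <- purrr::imap(cells[ord], function(cell, i) {
    tr <- cell$member$truth
    mut <- cell$member$mutations
    aligned_len <- tr$v_anchor_q  # pre-anchor germline V span
    n_mut <- nrow(mut)
    tibble::tibble(
      sequence_id = ids[i], sample_id = sample_id,
      sequence = cell$member$sequence,
      v_name = tr$v_name, d_name = tr$d_name, j_name = tr$j_name,
      v_gene = tr$v_gene, clone_id = cell$clone_id,
      shm = cell$shm,
      n_mutations = n_mut,
      positions = mutations_string(mut),
      junction = tr$junction, cdr3 = tr$cdr3,
      productive = check_productive(cell$member$sequence, tr),
      v_mutation_freq_pct = n_mut / aligned_len * 100,
      mutation_status = classify_mutation_status(n_mut)
    )
  })
  truth <- dplyr::bind_rows(rows)
  list(
    cells = truth[, c("sequence_id", "sample_id", "sequence")],
    truth = truth,
    truth_summary = truth_summary(truth)
  )
}

# SHM may create stops in the V region, so productivity is re-derived from
# the final sequence (frame anchored at the 2nd-CYS codon)
check_productive <- function(sequence, tr) {
  if (nchar(tr$junction) %% 3L != 0L) return(FALSE)
  frame_start <- tr$v_anchor_q %% 3L
  !has_stop(substr(sequence, frame_start + 1L, nchar(sequence)))
}

# a new recombination event must not resemble any prior event it could be
# confused with: events on different V genes (or with grossly different
# CDR3 lengths) can never co-clone under the clone rule, so only same-V,
# near-length events are alignment-screened for CDR3 divergence
event_separated <- function(cdr3, v_gene, accepted, accepted_vgene,
                            min_divergence_pct) {
  if (length(accepted) == 0L) return(TRUE)
  lens <- nchar(accepted)
  near <- accepted_vgene == v_gene &
    abs(lens - nchar(cdr3)) / pmax(lens, nchar(cdr3)) * 100 <= 15
  if (!any(near)) return(TRUE)
  all(cdr3_identity_many(cdr3, accepted[near]) < 100 - min_divergence_pct)
}

# per-sample summary over the truth table, via the same code path the
# pipeline uses on called clones; clone membership is restricted to
# productive cells, mirroring the pipeline default (non-productive members
# fall out as singletons)
truth_summary <- function(truth, productive_only = TRUE) {
  pseudo <- truth
  pseudo$clone_id <- paste0(pseudo$sample_id, "_", pseudo$clone_id)
  if (productive_only) {
    np <- which(!pseudo$productive)
    pseudo$clone_id[np] <- paste0(pseudo$sample_id[np], "_np", seq_along(np))
  }
  pseudo$v_mutation_positions <- pseudo$positions
  pseudo$.row <- seq_len(nrow(pseudo))
  summarize_samples(annotate_clone_columns(pseudo))
}
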