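# Shared fixtures, built in code at load time (fully deterministic).

fixture_ref <- synthetic_germline_set(seed = 101)
fixture_ref_d10 <- synthetic_germline_set(n_d = 10L, seed = 202)

fixture_v <- fixture_ref[fixture_ref$segment_class == "V", ]
fixture_d <- fixture_ref[fixture_ref$segment_class == "D", ]
fixture_j <- fixture_ref[fixture_ref$segment_class == "J", ]

random_dna_str <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

substitute_at <- function(seq, pos1, base) {
  substr(seq, pos1, pos1) <- base
  seq
}

# plant k substitutions at distinct 1-based positions, never to the same base
mutate_seq <- function(seq, positions, seed = 1) {
  set.seed(seed)
  for (p in positions) {
    old <- substr(seq, p, p)
    seq <- substitute_at(seq, p, sample(setdiff(c("A", "C", "G", "T"), old), 1))
  }
  seq
}

# write a simulated sample plus germline reference to disk as pipeline inputs
write_sim_inputs <- function(sim, dir, ref = fixture_ref) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fa <- file.path(dir, "cells.fasta")
  seqs <- Biostrings::DNAStringSet(sim$cells$sequence)
  names(seqs) <- sim$cells$sequence_id
  Biostrings::writeXStringSet(seqs, fa, width = 70L)
  paths <- list(
    input = fa,
    v = file.path(dir, "v.fasta"), d = file.path(dir, "d.fasta"),
    j = file.path(dir, "j.fasta"),
    manifest = file.path(dir, "manifest.tsv")
  )
  write_germline_fasta(germline_segment(ref, "V"), paths$v)
  write_germline_fasta(germline_segment(ref, "D"), paths$d)
  write_germline_fasta(germline_segment(ref, "J"), paths$j)
  readr::write_tsv(sim$cells[, c("sequence_id", "sample_id")], paths$manifest)
  paths
}

# truth-shaped rearrangement table (skips alignment) for clone-rule tests
truth_as_rearr <- function(truth) {
  out <- truth
  out$v_mutation_positions <- truth$positions
  out$v_mutation_freq_pct <- truth$v_mutation_freq_pct
  out
}
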