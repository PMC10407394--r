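# minimal clone-callable table
clone_input <- function(v_gene, cdr3, sample_id = "S1", status = "unmutated",
                        positions = "") {
  n <- length(cdr3)
  tibble::tibble(
    sequence_id = sprintf("c%02d", seq_len(n)),
    sample_id = rep_len(sample_id, n),
    v_gene = rep_len(v_gene, n),
    cdr3 = cdr3,
    productive = TRUE,
    mutation_status = rep_len(status, n),
    v_mutation_positions = rep_len(positions, n),
    v_mutation_freq_pct = 0
  )
}

partition_of <- function(called) {
  split(called$sequence_id, called$clone_id)
}

test_that("cdr3 identity follows global-alignment arithmetic and is symmetric", {
  a <- "ACGTACGTACGTACGTACGTACGTACGTAC"
  expect_equal(cdr3_identity(a, a), 100)
  b10 <- "ACGTACGTAC"
  expect_equal(cdr3_identity(b10, mutate_seq(b10, 4, seed = 2)), 90)
  set.seed(12)
  for (i in 1:20) {
    x <- random_dna_str(sample(9:30, 1))
    y <- mutate_seq(x, sample(nchar(x), 2), seed = i)
    expect_equal(cdr3_identity(x, y), cdr3_identity(y, x))
  }
  expect_error(cdr3_identity("", "ACGT"))
})

test_that("cdr3 identity agrees with an independent affine-gap DP oracle", {
  set.seed(91)
  for (i in 1:60) {
    la <- sample(9:22, 1)
    x <- random_dna_str(la)
    y <- if (i %% 3 == 0) {
      random_dna_str(sample(9:22, 1))          # unrelated pair
    } else {
      z <- mutate_seq(x, sample(la, sample(0:3, 1)), seed = 1000 + i)
      if (i %% 4 == 0) paste0(z, random_dna_str(3)) else z  # occasional indel
    }
    orc <- oracle_global_identity_set(x, y)
    expect_true(cdr3_identity(x, y) %in% orc$identities,
                info = paste(x, y))
  }
})

test_that("length compatibility uses the longer sequence and includes the boundary", {
  p <- clone_policy()
  expect_true(length_compatible(strrep("A", 40), strrep("A", 40), p))
  expect_true(length_compatible(strrep("A", 40), strrep("A", 42), p))  # 5.0%
  expect_false(length_compatible(strrep("A", 15), strrep("A", 13), p)) # 13.3%
})

test_that("clone membership needs same V gene, compatible length and >90% identity", {
  cdr3 <- "ACGTACGTACGTACGTACGT"
  same <- call_clones(clone_input("IGHV3-23", c(cdr3, cdr3)))
  expect_equal(length(unique(same$clone_id)), 1L)
  expect_equal(unique(same$clone_size), 2L)

  diffv <- call_clones(clone_input(c("IGHV3-23", "IGHV3-30"), c(cdr3, cdr3)))
  expect_equal(length(unique(diffv$clone_id)), 2L)
})

test_that("the identity threshold is strict and the length threshold inclusive", {
  # 10-nt pair at exactly 90.0% identity: NOT co-clonal
  a <- "ACGTACGTAC"
  b <- mutate_seq(a, 5, seed = 4)
  expect_equal(cdr3_identity(a, b), 90)
  called <- call_clones(clone_input("IGHV1-18", c(a, b)))
  expect_equal(length(unique(called$clone_id)), 2L)
  # 20-nt pair with 1 substitution (95%) IS co-clonal
  c20 <- "ACGTACGTACGTACGTACGT"
  called2 <- call_clones(clone_input("IGHV1-18", c(c20, mutate_seq(c20, 7, seed = 5))))
  expect_equal(length(unique(called2$clone_id)), 1L)
  # exactly 5% length difference with high identity merges
  a40 <- random_dna_str(40, seed = 8)
  b42 <- paste0(a40, "GT")
  expect_true(cdr3_identity(a40, b42) > 90)
  called3 <- call_clones(clone_input("IGHV1-18", c(a40, b42)))
  expect_equal(length(unique(called3$clone_id)), 1L)
})

test_that("clone calling recovers a planted truth partition (ARI 1.0)", {
  cfg <- sim_config(
    n_cells = 30,
    clone_spec = data.frame(size = c(5L, 3L, 2L),
                            mutated = c(TRUE, TRUE, FALSE),
                            extra_mut = c(0, 0, 0)),
    seed = 71)
  sim <- simulate_repertoire(cfg, fixture_ref)
  called <- call_clones(truth_as_rearr(sim$truth))
  keep <- sim$truth$productive
  expect_equal(oracle_ari(called$clone_id[keep], sim$truth$clone_id[keep]), 1)
})

test_that("every emitted multi-member clone satisfies complete linkage", {
  sim <- simulate_repertoire(sim_config(n_cells = 60, seed = 83), fixture_ref)
  called <- call_clones(truth_as_rearr(sim$truth))
  p <- clone_policy()
  for (cid in unique(called$clone_id[called$clone_size >= 2])) {
    members <- called[called$clone_id == cid, ]
    pairs <- utils::combn(nrow(members), 2)
    for (k in seq_len(ncol(pairs))) {
      a <- members$cdr3[pairs[1, k]]
      b <- members$cdr3[pairs[2, k]]
      expect_true(length_compatible(a, b, p))
      expect_gt(cdr3_identity(a, b), p$cdr3_min_identity_pct)
      expect_equal(members$v_gene[pairs[1, k]], members$v_gene[pairs[2, k]])
    }
  }
})

test_that("the partition is invariant under input order", {
  sim <- simulate_repertoire(sim_config(n_cells = 40, seed = 29), fixture_ref)
  base <- call_clones(truth_as_rearr(sim$truth))
  base_part <- partition_of(base)
  for (s in 1:5) {
    set.seed(s)
    shuf <- truth_as_rearr(sim$truth)[sample(nrow(sim$truth)), ]
    part <- partition_of(call_clones(shuf))
    expect_setequal(
      unname(vapply(base_part, function(x) paste(sort(x), collapse = "+"), "")),
      unname(vapply(part, function(x) paste(sort(x), collapse = "+"), "")))
  }
})

test_that("intraclonal diversity counts distinct mutation patterns", {
  cdr3 <- "ACGTACGTACGTACGTAC"
  # three byte-identical members: no diversity
  same <- call_clones(clone_input("IGHV3-7", rep(cdr3, 3), status = "mutated",
                                  positions = "10:A>G;40:C>T"))
  expect_equal(unique(same$n_variants), 1L)
  expect_false(any(same$intraclonal_diversity))
  # one member carries two extra mutations: diversity, 2 variants
  tab <- clone_input("IGHV3-7", rep(cdr3, 3), status = "mutated",
                     positions = "10:A>G;40:C>T")
  tab$v_mutation_positions[3] <- "10:A>G;40:C>T;55:G>A;80:T>C"
  div <- call_clones(tab)
  expect_equal(unique(div$n_variants), 2L)
  expect_true(all(div$intraclonal_diversity))
  # singletons are never diverse
  single <- call_clones(clone_input("IGHV3-7", cdr3))
  expect_false(any(single$intraclonal_diversity))
})

test_that("records without a CDR3 fall out as unclustered singletons", {
  tab <- clone_input("IGHV3-7", c("ACGTACGTACGT", "ACGTACGTACGT"))
  tab$cdr3[2] <- NA_character_
  called <- call_clones(tab)
  expect_equal(sum(called$clone_unclustered), 1L)
  expect_equal(length(unique(called$clone_id)), 2L)
})

test_that("per-sample summaries mirror the expected arithmetic", {
  cdr3a <- "ACGTACGTACGTACGTACGT"
  tab <- clone_input("IGHV3-23",
                     c(cdr3a, cdr3a, "TTTTGGGGCCCCAAAATTGC", "GGCCATATGGCCATAACGTA"),
                     status = c("mutated", "mutated", "unmutated", "mutated"))
  tab$v_mutation_freq_pct <- c(4, 4, 0, 6)
  called <- call_clones(tab)
  s <- summarize_samples(called)
  expect_equal(s$pct_mutated, 75.0)
  expect_equal(s$n_cells_with_ighv, 4L)
  expect_equal(s$clones_mutated, "1x 2 cells")
  expect_equal(s$clones_unmutated, "0")
  expect_equal(s$mean_freq_of_mutated, round(mean(c(4, 4, 6)), 1))
  usage <- s$v_gene_usage[[1]]
  expect_equal(sum(usage$n_productive), 4L)
})

test_that("the rendered summary table mirrors the expanded-clone inventory format", {
  summaries <- tibble::tibble(
    sample_id = "case2", n_cells_with_ighv = 36L, pct_mutated = 61.1,
    mean_freq_of_mutated = 3.2,
    clones_unmutated = ighvclones:::clone_inventory_string(c(2, 2)),
    clones_mutated = ighvclones:::clone_inventory_string(c(2, 2, 3)),
    n_clones_expanded = 5L, n_clones_mutated = 3L, n_clones_unmutated = 2L,
    n_clones_with_diversity = 1L,
    v_gene_usage = list(tibble::tibble(v_gene = "IGHV3-23", n_productive = 36L))
  )
  expect_equal(summaries$clones_unmutated, "2x 2 cells")
  expect_equal(summaries$clones_mutated, "2x 2 cells,1x 3 cells")
  lines <- render_summary_table(summaries)
  expect_length(lines, 2L)
  expect_match(lines[2], "^case2\t36\t61.1\t3.2\t2x 2 cells\t2x 2 cells,1x 3 cells\t1$")
  # no expanded clones renders "0" in both columns
  none <- summaries
  none$clones_unmutated <- ighvclones:::clone_inventory_string(integer())
  none$clones_mutated <- ighvclones:::clone_inventory_string(integer())
  expect_match(render_summary_table(none)[2], "\t0\t0\t", fixed = FALSE)
})
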