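test_that("an exact germline copy aligns to its own gene at 100% identity", {
  v <- fixture_v[fixture_v$name == "IGHV3-30*01", ]
  hit <- assign_v_gene(substr(v$sequence, 1, 280), fixture_ref)
  expect_equal(hit$gene, "IGHV3-30*01")
  expect_equal(hit$identity_pct, 100)
  expect_equal(hit$n_mismatches, 0L)
  expect_equal(hit$q_start, 0L)
  expect_equal(hit$g_start, 0L)
})

test_that("V assignment survives seeded substitutions and matches the counts", {
  v <- fixture_v[fixture_v$name == "IGHV3-30*01", ]
  query <- mutate_seq(substr(v$sequence, 10, 280),
                      positions = seq(20, 230, by = 15), seed = 11)
  n_sub <- length(seq(20, 230, by = 15))
  hit <- assign_v_gene(query, fixture_ref)
  expect_equal(hit$gene, "IGHV3-30*01")
  expect_equal(hit$n_mismatches, n_sub)
  span <- hit$q_end - hit$q_start
  expect_equal(hit$identity_pct, (span - n_sub) / span * 100)
})

test_that("V scores equal an independent Smith-Waterman oracle on a 3-gene fixture", {
  genes3 <- fixture_v[1:3, ]
  short <- substr(genes3$sequence, 1, 100)
  set.seed(31)
  for (rep in 1:4) {
    base <- short[(rep %% 3) + 1]
    query <- mutate_seq(base, positions = sample(100, 8), seed = 31 + rep)
    mine <- vapply(short, function(g) {
      ighvclones:::align_local_batch(query, g)$score
    }, numeric(1))
    oracle <- vapply(short, function(g) {
      oracle_align_score(query, g, type = "local")
    }, numeric(1))
    expect_equal(unname(mine), unname(oracle))
  }
})

test_that("random DNA gets no V assignment", {
  expect_error(assign_v_gene(random_dna_str(120, seed = 5), fixture_ref),
               "no V assignment")
})

test_that("J assignment recovers the gene and its 5' trim", {
  v <- fixture_v[1, ]
  j <- fixture_j[2, ]
  vhit_seq <- v$sequence
  # intact J appended after a 4-nt N region
  q1 <- paste0(vhit_seq, "ACGT", j$sequence)
  vhit <- assign_v_gene(q1, fixture_ref)
  jhit <- assign_j_gene(q1, fixture_ref, vhit, v_anchor_q = v$anchor)
  expect_equal(jhit$gene, j$name)
  expect_equal(jhit$identity_pct, 100)
  expect_equal(jhit$g_start, 0L)
  # J trimmed by 5 nt at its 5' end
  q2 <- paste0(vhit_seq, "ACGT", substr(j$sequence, 6, nchar(j$sequence)))
  jhit2 <- assign_j_gene(q2, fixture_ref, vhit, v_anchor_q = v$anchor)
  expect_equal(jhit2$gene, j$name)
  expect_equal(jhit2$g_start, 5L)
  # sequence truncated before any J
  q3 <- substr(vhit_seq, 1, 270)
  expect_error(assign_j_gene(q3, fixture_ref, assign_v_gene(q3, fixture_ref),
                             v_anchor_q = v$anchor),
               "no J assignment")
})

test_that("junction extraction matches simulator truth at SHM rate 0", {
  cfg <- sim_config(n_cells = 15, mutated_fraction = 0,
                    clone_spec = data.frame(size = integer(),
                                            mutated = logical(),
                                            extra_mut = numeric()),
                    seed = 23)
  sim <- simulate_repertoire(cfg, fixture_ref)
  ann <- annotate_rearrangements(sim$cells, fixture_ref)
  j <- dplyr::inner_join(ann, sim$truth, by = "sequence_id",
                         suffix = c("", ".truth"))
  expect_equal(j$junction, j$junction.truth)
  expect_equal(j$cdr3, j$cdr3.truth)
  expect_equal(j$v_call, j$v_name)
  expect_equal(j$j_call, j$j_name)
  expect_true(all(j$productivity == "productive"))
})

test_that("junction arithmetic holds when V and J anchors abut with no N region", {
  v <- fixture_v[1, ]
  j <- fixture_j[1, ]
  # V through its end (6 nt past the anchor codon) + J from its start:
  # junction = 9 V bases + 9 J pre-anchor bases + 3 anchor bases
  q <- paste0(v$sequence, j$sequence)
  vhit <- assign_v_gene(q, fixture_ref)
  jhit <- assign_j_gene(q, fixture_ref, vhit, v_anchor_q = v$anchor)
  jr <- extract_junction(q, vhit, jhit, fixture_ref)
  expect_equal(jr$junction_length, (285 - 276) + 9 + 3)
  expect_equal(nchar(jr$cdr3), jr$junction_length - 6)
})

test_that("a V alignment ending before the anchor leaves the junction unresolved", {
  v <- fixture_v[1, ]
  j <- fixture_j[1, ]
  q <- paste0(substr(v$sequence, 1, 250), j$sequence)  # V cut 26 nt pre-anchor
  vhit <- assign_v_gene(q, fixture_ref)
  jhit <- assign_j_gene(q, fixture_ref, vhit)
  expect_null(extract_junction(q, vhit, jhit, fixture_ref))
})

test_that("D assignment requires at least a 7-base exact run", {
  d <- fixture_d[1, ]
  flank1 <- "CCATAG"  # low-complexity flanks keep spurious runs short
  cdr3_7 <- paste0(flank1, substr(d$sequence, 3, 9), "GGTAC")
  res7 <- assign_d_gene(cdr3_7, fixture_ref)
  expect_false(is.null(res7))
  expect_gte(res7$run_length, 7L)
  # oracle agreement on the same input
  orc <- oracle_assign_d(cdr3_7, fixture_d$name, fixture_d$sequence)
  expect_equal(res7$gene, orc$gene)
  expect_equal(res7$run_length, orc$run)
})

test_that("D assignment matches the brute-force substring oracle on random CDR3s", {
  set.seed(77)
  dset <- fixture_ref_d10[fixture_ref_d10$segment_class == "D", ]
  n6 <- 0; n7 <- 0
  for (i in 1:60) {
    cdr3 <- random_dna_str(sample(12:40, 1))
    mine <- assign_d_gene(cdr3, fixture_ref_d10)
    orc <- oracle_assign_d(cdr3, dset$name, dset$sequence)
    if (is.null(orc)) {
      expect_null(mine)
    } else {
      expect_equal(mine$gene, orc$gene)
      expect_equal(mine$run_length, orc$run)
    }
    best <- max(vapply(dset$sequence, function(d) oracle_lcs(cdr3, d),
                       integer(1)))
    if (best == 6L) n6 <- n6 + 1
    if (best == 7L) n7 <- n7 + 1
  }
  # the random draw exercised both sides of the run-length boundary
  expect_gt(n6 + n7, 0)
})

test_that("productivity classification follows frame and stop codons", {
  cfg <- sim_config(n_cells = 8, seed = 41)
  sim <- simulate_repertoire(cfg, fixture_ref)
  ann <- annotate_rearrangements(sim$cells, fixture_ref)
  prodrow <- ann[which(ann$productivity == "productive")[1], ]
  # delete 1 nt inside the CDR3 (N region): frame shift -> nonproductive
  pos <- prodrow$v_anchor_q + 5L
  shifted <- paste0(substr(prodrow$sequence, 1, pos),
                    substr(prodrow$sequence, pos + 2, nchar(prodrow$sequence)))
  ann2 <- annotate_rearrangements(
    tibble::tibble(sequence_id = "x", sequence = shifted), fixture_ref)
  expect_equal(ann2$productivity, "nonproductive")
  # junction-unresolved record is unresolved
  expect_equal(classify_productivity("ACGT", NULL), "unresolved")
})

test_that("annotation is deterministic across runs", {
  sim <- simulate_repertoire(sim_config(n_cells = 8, seed = 19), fixture_ref)
  a1 <- annotate_rearrangements(sim$cells, fixture_ref)
  a2 <- annotate_rearrangements(sim$cells, fixture_ref)
  expect_identical(a1, a2)
})
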