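# Internal alignment machinery shared by V/J assignment, CDR3 identity and
# mutation counting. One fixed nucleotide scoring scheme everywhere:
# match +1, mismatch -1, gap open -4, gap extend -1 per base, and 'N'
# never matches anything (scores as a mismatch, even against 'N').

ALN_GAP_OPEN <- 4
ALN_GAP_EXT <- 1

aln_submat <- function() {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(-1, 5L, 5L, dimnames = list(b, b))
  diag(m) <- 1
  m["N", ] <- -1
  m[, "N"] <- -1
  m
}

# Local alignment of a batch of queries against ONE germline sequence
# (one pairwiseAlignment call: the S4 overhead is per call, so batching
# across cells is what keeps whole-sample annotation fast). Returns a
# tibble with one row per query: score, 0-based half-open spans, identity
# over aligned columns, mismatch/indel counts, aligned strings.
align_local_batch <- function(queries, germ_seq) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAStringSet(queries),
    subject = Biostrings::DNAString(germ_seq),
    type = "local",
    substitutionMatrix = aln_submat(),
    gapOpening = ALN_GAP_OPEN, gapExtension = ALN_GAP_EXT
  )
  # as.character on the Aligned*XStringSet is orders of magnitude faster
  # than alignedPattern()/alignedSubject() and yields the same gapped strings
  q_al <- unname(as.character(Biostrings::pattern(aln)))
  g_al <- unname(as.character(Biostrings::subject(aln)))
  cols <- nchar(g_al)
  nm <- Biostrings::nmatch(aln)
  tibble::tibble(
    score = as.numeric(Biostrings::score(aln)),
    identity_pct = ifelse(cols > 0, nm / cols * 100, 0),
    q_start = BiocGenerics::start(Biostrings::pattern(aln)) - 1L,
    q_end = BiocGenerics::end(Biostrings::pattern(aln)),
    g_start = BiocGenerics::start(Biostrings::subject(aln)) - 1L,
    g_end = BiocGenerics::end(Biostrings::subject(aln)),
    n_mismatches = as.integer(Biostrings::nmismatch(aln)),
    n_insertions = as.integer(stringr::str_count(g_al, "-")),
    n_deletions = as.integer(stringr::str_count(q_al, "-")),
    germ_aligned = g_al,
    query_aligned = q_al
  )
}

# One query against a set of germlines (thin wrapper over the batch path).
align_local_set <- function(query, germ_seqs, germ_names) {
  rows <- lapply(germ_seqs, function(g) align_local_batch(query, g))
  out <- dplyr::bind_rows(rows)
  out$gene <- germ_names
  out[, c("gene", setdiff(names(out), "gene"))]
}

# Batch best-hit assignment: queries x germline set, deterministic
# tie-breaking as in pick_best_alignment. Returns one row per query.
assign_segment_batch <- function(queries, germ_seqs, germ_names) {
  per_gene <- lapply(germ_seqs, function(g) align_local_batch(queries, g))
  n <- length(queries)
  G <- length(germ_seqs)
  score <- vapply(per_gene, `[[`, numeric(n), "score")
  ident <- vapply(per_gene, `[[`, numeric(n), "identity_pct")
  span <- vapply(per_gene, function(t) as.numeric(t$q_end - t$q_start),
                 numeric(n))
  if (n == 1L) {
    score <- matrix(score, 1L); ident <- matrix(ident, 1L)
    span <- matrix(span, 1L)
  }
  name_rank <- rank(germ_names, ties.method = "first")
  best <- vapply(seq_len(n), function(i) {
    ord <- order(-score[i, ], -ident[i, ], -span[i, ], name_rank)
    ord[1]
  }, integer(1))
  out <- dplyr::bind_rows(lapply(seq_len(n), function(i) {
    per_gene[[best[i]]][i, ]
  }))
  out$gene <- germ_names[best]
  out[, c("gene", setdiff(names(out), "gene"))]
}

# Deterministic best hit: highest score, then higher identity, then longer
# aligned query span, then lexicographically smallest gene name.
pick_best_alignment <- function(hits) {
  ord <- order(-hits$score, -hits$identity_pct,
               -(hits$q_end - hits$q_start), hits$gene)
  hits[ord[1], , drop = FALSE]
}

# Column-by-column walk of a pairwise alignment. Returns one row per
# alignment column with 0-based germline/query positions (NA at gaps) and
# the two bases.
alignment_columns <- function(germ_aligned, query_aligned, g_start, q_start) {
  gb <- stringr::str_split_1(germ_aligned, "")
  qb <- stringr::str_split_1(query_aligned, "")
  g_pos <- cumsum(gb != "-") - 1L + g_start
  g_pos[gb == "-"] <- NA_integer_
  q_pos <- cumsum(qb != "-") - 1L + q_start
  q_pos[qb == "-"] <- NA_integer_
  tibble::tibble(g_pos = g_pos, q_pos = q_pos, g_base = gb, q_base = qb)
}

# Map a 0-based germline position to its 0-based query position through an
# alignment row (as produced by align_local_set). NA when the position is
# outside the aligned germline span or deleted in the query.
map_germline_to_query <- function(hit, g_position) {
  if (g_position < hit$g_start || g_position >= hit$g_end) return(NA_integer_)
  cols <- alignment_columns(hit$germ_aligned, hit$query_aligned,
                            hit$g_start, hit$q_start)
  i <- which(!is.na(cols$g_pos) & cols$g_pos == g_position)
  if (length(i) != 1L) return(NA_integer_)
  cols$q_pos[i]
}

GENETIC_CODE_X <- local({
  code <- as.character(Biostrings::GENETIC_CODE)
  names(code) <- names(Biostrings::GENETIC_CODE)
  code
})

# Translate DNA; codons containing anything outside ACGT become 'X'
# (an ambiguous base is never called a stop). Trailing partial codon dropped.
translate_dna <- function(nt) {
  n <- nchar(nt) %/% 3L
  if (n == 0L) return("")
  codons <- substring(nt, 3L * seq_len(n) - 2L, 3L * seq_len(n))
  aa <- GENETIC_CODE_X[codons]
  aa[is.na(aa)] <- "X"
  paste(aa, collapse = "")
}

has_stop <- function(nt) stringr::str_detect(translate_dna(nt), stringr::fixed("*"))
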