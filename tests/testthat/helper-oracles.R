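# Independent brute-force oracles, deliberately written without reusing any
# package internals: plain-R dynamic programming with explicit loops.

# Gotoh affine-gap alignment score (match +1, mismatch -1, opening a gap
# costs 4 plus 1 per gap base). type "local" (Smith-Waterman) or "global"
# (Needleman-Wunsch with penalised end gaps).
oracle_align_score <- function(a, b, type = c("global", "local")) {
  type <- match.arg(type)
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  open <- 5; ext <- 1  # first gap base costs open(4)+ext(1)=5
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  if (type == "local") {
    M[, 1] <- 0; M[1, ] <- 0
  } else {
    for (i in 2:(n + 1)) X[i, 1] <- -4 - (i - 1)
    for (j in 2:(m + 1)) Y[1, j] <- -4 - (j - 1)
  }
  best_local <- 0
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1] && av[i - 1] != "N") 1 else -1
      diag_best <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
      M[i, j] <- diag_best + s
      if (type == "local" && M[i, j] < 0) M[i, j] <- 0
      X[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - ext,
                     Y[i - 1, j] - open)
      Y[i, j] <- max(M[i, j - 1] - open, X[i, j - 1] - open,
                     Y[i, j - 1] - ext)
      if (type == "local" && M[i, j] > best_local) best_local <- M[i, j]
    }
  }
  if (type == "local") best_local else max(M[n + 1, m + 1], X[n + 1, m + 1],
                                           Y[n + 1, m + 1])
}

# All (matches, columns) pairs achievable by score-optimal global
# alignments: second pass over the Gotoh matrices collecting sets.
oracle_global_identity_set <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  open <- 5; ext <- 1
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)
  Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) X[i, 1] <- -4 - (i - 1)
  if (m >= 1) for (j in 2:(m + 1)) Y[1, j] <- -4 - (j - 1)
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) 1 else -1
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open, X[i - 1, j] - ext,
                     Y[i - 1, j] - open)
      Y[i, j] <- max(M[i, j - 1] - open, X[i, j - 1] - open,
                     Y[i, j - 1] - ext)
    }
  }
  # sets of "matches,columns" strings per cell/state, built forward
  sets <- array(vector("list", 3 * (n + 1) * (m + 1)),
                dim = c(n + 1, m + 1, 3))
  sets[[1, 1, 1]] <- "0,0"
  bump <- function(set, dm, dc) {
    if (is.null(set)) return(NULL)
    parts <- do.call(rbind, strsplit(set, ","))
    unique(paste(as.integer(parts[, 1]) + dm,
                 as.integer(parts[, 2]) + dc, sep = ","))
  }
  for (j in seq_len(m)) {
    prev <- if (j == 1) sets[[1, 1, 1]] else sets[[1, j, 3]]
    sets[[1, j + 1, 3]] <- bump(prev, 0, 1)
  }
  for (i in seq_len(n)) {
    prev <- if (i == 1) sets[[1, 1, 1]] else sets[[i, 1, 2]]
    sets[[i + 1, 1, 2]] <- bump(prev, 0, 1)
  }
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- if (av[i - 1] == bv[j - 1]) 1 else -1
      # M state
      accM <- character()
      for (st in 1:3) {
        pv <- switch(st, M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1])
        if (pv + s == M[i, j] && pv > NEG / 2) {
          accM <- c(accM, bump(sets[[i - 1, j - 1, st]],
                               as.integer(s == 1), 1))
        }
      }
      if (length(accM)) sets[[i, j, 1]] <- unique(accM)
      # X state (consume a[i-1], gap in b)
      accX <- character()
      cand <- c(M[i - 1, j] - open, X[i - 1, j] - ext, Y[i - 1, j] - open)
      for (st in 1:3) {
        if (cand[st] == X[i, j] && cand[st] > NEG / 2) {
          accX <- c(accX, bump(sets[[i - 1, j, st]], 0, 1))
        }
      }
      if (length(accX)) sets[[i, j, 2]] <- unique(accX)
      # Y state
      accY <- character()
      cand <- c(M[i, j - 1] - open, X[i, j - 1] - open, Y[i, j - 1] - ext)
      for (st in 1:3) {
        if (cand[st] == Y[i, j] && cand[st] > NEG / 2) {
          accY <- c(accY, bump(sets[[i, j - 1, st]], 0, 1))
        }
      }
      if (length(accY)) sets[[i, j, 3]] <- unique(accY)
    }
  }
  final <- c(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
  top <- max(final)
  out <- character()
  for (st in 1:3) {
    if (final[st] == top && !is.null(sets[[n + 1, m + 1, st]])) {
      out <- c(out, sets[[n + 1, m + 1, st]])
    }
  }
  parts <- do.call(rbind, strsplit(unique(out), ","))
  ident <- as.integer(parts[, 1]) / as.integer(parts[, 2]) * 100
  list(score = top, identities = ident)
}

# Brute-force longest common substring: try every substring of a, longest
# first, with fixed-string matching against b.
oracle_lcs <- function(a, b) {
  na <- nchar(a)
  for (len in seq(min(na, nchar(b)), 1)) {
    for (s in seq_len(na - len + 1)) {
      if (grepl(substr(a, s, s + len - 1), b, fixed = TRUE)) return(len)
    }
  }
  0L
}

# D assignment oracle: rule applied on top of oracle_lcs
oracle_assign_d <- function(cdr3, d_names, d_seqs, min_run = 7L) {
  runs <- vapply(d_seqs, function(d) oracle_lcs(cdr3, d), integer(1))
  best <- max(runs)
  if (best < min_run) return(NULL)
  list(gene = sort(d_names[runs == best])[1], run = best)
}

# Independent gapped-position counter: ungapped offset of IMGT gapped codon
# `codon` (1-based), scanning character by character.
oracle_gapped_codon_anchor <- function(gapped, codon = 104L) {
  chars <- strsplit(gapped, "")[[1]]
  target_start <- (codon - 1L) * 3L + 1L
  if (length(chars) < target_start + 2L) return(NA_integer_)
  if (any(chars[target_start:(target_start + 2L)] == ".")) return(NA_integer_)
  count <- 0L
  for (k in seq_len(target_start - 1L)) {
    if (chars[k] != ".") count <- count + 1L
  }
  count
}

# adjusted Rand index between two partitions given as label vectors
oracle_ari <- function(a, b) mclust::adjustedRandIndex(a, b)
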