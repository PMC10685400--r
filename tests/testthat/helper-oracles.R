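# Independent oracles used across the suite. These are deliberately plain
# re-derivations (direct formulas, exhaustive enumeration, simple DP) kept
# separate from the package's own code paths.

blosum62_matrix <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
}

# --- Gotoh affine-gap global alignment score (independent DP) -------------
oracle_nw_score <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # ends in match/mismatch
  X <- matrix(NEG, n + 1, m + 1)   # ends in gap in B (A consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # ends in gap in A (B consumed)
  M[1, 1] <- 0
  for (i in 2:(n + 1)) X[i, 1] <- -gap_open - (i - 1) * gap_extend
  for (j in 2:(m + 1)) Y[1, j] <- -gap_open - (j - 1) * gap_extend
  for (i in 2:(n + 1)) {
    for (j in 2:(m + 1)) {
      s <- submat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - gap_open - gap_extend,
                     X[i - 1, j] - gap_extend)
      Y[i, j] <- max(M[i, j - 1] - gap_open - gap_extend,
                     Y[i, j - 1] - gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# --- exhaustive maximal-clique enumeration over all 2^n subsets ----------
# adjacency as logical matrix; returns list of sorted integer vectors in
# lexicographic order (same canonical order as the package's output)
oracle_maximal_cliques <- function(adj) {
  n <- nrow(adj)
  if (n == 0L) return(list())
  nbr_mask <- integer(n)
  for (i in seq_len(n))
    nbr_mask[i] <- sum(bitwShiftL(1L, which(adj[i, ]) - 1L))
  is_clique <- function(mask) {
    v <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    for (i in v) {
      others <- bitwAnd(mask, bitwNot(bitwShiftL(1L, i - 1L)))
      if (bitwAnd(others, nbr_mask[i]) != others) return(FALSE)
    }
    TRUE
  }
  cliques <- list()
  masks <- integer(0)
  for (mask in seq_len(2^n - 1L)) {
    if (!is_clique(mask)) next
    # maximal: no vertex outside adjacent to all members
    extendable <- FALSE
    for (u in seq_len(n)) {
      ubit <- bitwShiftL(1L, u - 1L)
      if (bitwAnd(mask, ubit) != 0L) next
      if (bitwAnd(nbr_mask[u], mask) == mask) { extendable <- TRUE; break }
    }
    if (!extendable) {
      cliques[[length(cliques) + 1L]] <-
        which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    }
  }
  ord <- order(vapply(cliques, function(cl)
    paste(sprintf("%06d", cl), collapse = " "), ""))
  cliques[ord]
}

# --- exhaustive best-design search over all valid mutation subsets -------
# singles: data frame (mutation, pos, ddg); antagonism decided from the
# supplied pair ddG lookup (function(mut_a, mut_b) -> value)
oracle_best_design <- function(singles, pair_fun) {
  n <- nrow(singles)
  best <- NULL
  for (mask in 0:(2^n - 1L)) {
    idx <- which(bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L)
    if (length(idx) == 0L) next
    ok <- !anyDuplicated(singles$pos[idx])
    if (ok && length(idx) >= 2L) {
      for (i in idx) {
        for (j in idx[idx > i]) {
          pd <- pair_fun(singles$mutation[i], singles$mutation[j])
          if (pd > min(singles$ddg[i], singles$ddg[j])) { ok <- FALSE; break }
        }
        if (!ok) break
      }
    }
    if (!ok) next
    cand <- list(idx = idx, score = sum(singles$ddg[idx]),
                 size = length(idx),
                 key = paste(sprintf("%06d", sort(singles$pos[idx])),
                             collapse = " "))
    if (is.null(best) ||
        cand$score < best$score - 1e-12 ||
        (abs(cand$score - best$score) <= 1e-12 &&
         (cand$size > best$size ||
          (cand$size == best$size && cand$key < best$key)))) {
      best <- cand
    }
  }
  best
}

# --- direct-formula information scores on tiny alignments ----------------
oracle_mi <- function(col_a, col_b) {
  ok <- col_a %in% stabiliforge:::AA_ALPHABET &
    col_b %in% stabiliforge:::AA_ALPHABET
  a <- col_a[ok]; b <- col_b[ok]
  n <- length(a)
  if (n < 2) return(0)
  mi <- 0
  for (x in unique(a)) {
    for (y in unique(b)) {
      pxy <- sum(a == x & b == y) / n
      if (pxy > 0)
        mi <- mi + pxy * log2(pxy / ((sum(a == x) / n) * (sum(b == y) / n)))
    }
  }
  mi
}

oracle_omes <- function(col_a, col_b) {
  ok <- col_a %in% stabiliforge:::AA_ALPHABET &
    col_b %in% stabiliforge:::AA_ALPHABET
  a <- col_a[ok]; b <- col_b[ok]
  n <- length(a)
  if (n < 2) return(0)
  s <- 0
  for (x in unique(a)) {
    for (y in unique(b)) {
      nobs <- sum(a == x & b == y)
      nexp <- sum(a == x) * sum(b == y) / n
      s <- s + (nobs - nexp)^2 / n
    }
  }
  s
}

oracle_jsd <- function(p, q) {
  r <- (p + q) / 2
  kl <- function(u, v) sum(ifelse(u > 0, u * log2(u / v), 0))
  0.5 * kl(p, r) + 0.5 * kl(q, r)
}

# entropy in bits of a discrete sample
oracle_entropy <- function(x) {
  p <- table(x) / length(x)
  -sum(p * log2(p))
}

# --- linear-scan back-to-consensus oracle --------------------------------
oracle_consensus_calls <- function(msa_obj) {
  mat <- msa_obj$mat
  out <- list()
  qchars <- strsplit(msa_obj$query_seq, "")[[1]]
  for (cc in which(!is.na(msa_obj$colmap))) {
    col <- mat[, cc]
    col <- col[col %in% stabiliforge:::AA_ALPHABET]
    if (!length(col)) next
    qpos <- msa_obj$colmap[cc]
    wt <- qchars[qpos]
    tab <- table(factor(col, levels = stabiliforge:::AA_ALPHABET))
    freqs <- as.numeric(tab) / sum(tab)
    names(freqs) <- names(tab)
    cons <- names(freqs)[which.max(freqs)]
    if (cons == wt) next
    fc <- freqs[[cons]]
    fw <- if (wt %in% names(freqs)) freqs[[wt]] else 0
    if (fc >= 0.5) {
      out[[length(out) + 1L]] <- list(pos = qpos, mut = cons,
                                      src = "consensus-majority")
    } else if (fc >= 0.4 && fc >= 5 * fw) {
      out[[length(out) + 1L]] <- list(pos = qpos, mut = cons,
                                      src = "consensus-ratio")
    }
  }
  out
}

# random symmetric matrix with zero diagonal
random_symmetric <- function(n, seed) {
  set.seed(seed)
  m <- matrix(runif(n * n), n, n)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

# random adjacency matrix (Erdos-Renyi)
random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  m <- matrix(FALSE, n, n)
  m[upper.tri(m)] <- runif(n * (n - 1) / 2) < p
  m | t(m)
}
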