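# Per-column conservation (Jensen-Shannon divergence against a background
# distribution, 0-9 grades) and inter-column coevolution scores (MI, OMES,
# McBASC, APC-corrected MI, plus user plugins) combined into a consensus
# correlated-position call.

# integer codes 1..20 for standard residues, 0 for gaps/ambiguous
.msa_codes <- function(msa_obj) {
  m <- match(msa_obj$mat, AA_ALPHABET)
  m[is.na(m)] <- 0L
  matrix(m, nrow = nrow(msa_obj$mat))
}

#' Per-column amino-acid profile of an alignment
#'
#' @param msa_obj an \code{msa}.
#' @return list with \code{counts} (20 x ncol matrix), \code{freqs}
#'   (columns normalised over non-gap symbols), \code{gap_fraction} and
#'   \code{depth}.
#' @export
column_profile <- function(msa_obj) {
  codes <- .msa_codes(msa_obj)
  nc <- ncol(codes)
  counts <- vapply(seq_len(nc), function(j) {
    tabulate(codes[, j], nbins = 20L)
  }, integer(20))
  counts <- matrix(counts, nrow = 20, dimnames = list(AA_ALPHABET, NULL))
  tot <- colSums(counts)
  freqs <- sweep(counts, 2, pmax(tot, 1), "/")
  list(counts = counts, freqs = freqs,
       gap_fraction = 1 - tot / nrow(codes), depth = nrow(codes))
}

.kl2 <- function(p, q) {
  nz <- p > 0
  sum(p[nz] * log2(p[nz] / q[nz]))
}

.jsd <- function(p, q) {
  r <- (p + q) / 2
  0.5 * .kl2(p, r) + 0.5 * .kl2(q, r)
}

#' Jensen-Shannon conservation scores
#'
#' Each column's residue distribution p is compared with a background
#' distribution q via the Jensen-Shannon divergence (log base 2, bounded in
#' [0,1]); the raw score is damped by the column's gap fraction and then
#' smoothed over a sequence window: the final score is
#' \code{(1 - window_weight) * own + window_weight * mean(neighbours)} over
#' up to \code{window} columns on each side. High scores mean strong
#' conservation (far from background).
#'
#' @param msa_obj an \code{msa} of depth >= 2.
#' @param background 20-amino-acid probability vector (defaults to the
#'   BLOSUM62 background frequencies).
#' @param window columns on each side used for smoothing (0 disables).
#' @param window_weight weight of the window mean in the final score.
#' @return numeric vector of per-column scores in [0, 1].
#' @export
jsd_conservation <- function(msa_obj, background = BLOSUM62_BACKGROUND,
                             window = 3, window_weight = 0.5) {
  stopifnot(nrow(msa_obj$mat) >= 2)
  q <- background / sum(background)
  prof <- column_profile(msa_obj)
  if (all(prof$gap_fraction >= 1)) stop("alignment contains only gaps")
  raw <- vapply(seq_len(ncol(prof$freqs)), function(j) {
    if (prof$gap_fraction[j] >= 1) return(0)
    .jsd(prof$freqs[, j], q) * (1 - prof$gap_fraction[j])
  }, 0)
  if (window <= 0 || window_weight <= 0) return(raw)
  n <- length(raw)
  smoothed <- vapply(seq_len(n), function(j) {
    nb <- setdiff(max(1, j - window):min(n, j + window), j)
    (1 - window_weight) * raw[j] + window_weight * mean(raw[nb])
  }, 0)
  smoothed
}

#' Discretise conservation scores into 0-9 grades
#'
#' Grade of a column is \code{min(9, floor(10 * f))} where f is the fraction
#' of columns with strictly greater conservation score; the most conserved
#' column gets grade 0.
#'
#' @param scores per-column conservation scores.
#' @return integer vector of grades in 0..9.
#' @export
conservation_grades <- function(scores) {
  stopifnot(length(scores) >= 1)
  n <- length(scores)
  vapply(scores, function(s) {
    min(9L, as.integer(floor(10 * sum(scores > s) / n)))
  }, integer(1))
}

# ---------------------------------------------------------------------------
# Coevolution matrices. All return symmetric matrices with zero diagonal.

# apply FUN(i, j) over all column pairs into a symmetric matrix
.pair_matrix <- function(nc, FUN) {
  out <- matrix(0, nc, nc)
  for (i in seq_len(nc - 1L)) {
    for (j in seq(i + 1L, nc)) {
      v <- FUN(i, j)
      out[i, j] <- v
      out[j, i] <- v
    }
  }
  out
}

#' Mutual information between alignment columns
#'
#' MI(i,j) in bits over sequences non-gapped at both columns; pairs with
#' fewer than two jointly non-gapped sequences score 0.
#'
#' @param msa_obj an \code{msa} of depth >= 2.
#' @return symmetric matrix of MI values (bits), zero diagonal.
#' @export
mi_matrix <- function(msa_obj) {
  codes <- .msa_codes(msa_obj)
  .pair_matrix(ncol(codes), function(i, j) {
    ok <- codes[, i] > 0L & codes[, j] > 0L
    if (sum(ok) < 2L) return(0)
    a <- codes[ok, i]; b <- codes[ok, j]
    n <- length(a)
    joint <- table(a, b) / n
    pa <- rowSums(joint); pb <- colSums(joint)
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / outer(pa, pb)[nz]))
  })
}

#' Observed-minus-expected-squared coevolution score
#'
#' OMES(i,j) = sum over residue pairs of (N_obs - N_exp)^2 / N with
#' N_exp = N_x * N_y / N, over the N sequences non-gapped at both columns.
#'
#' @param msa_obj an \code{msa} of depth >= 2.
#' @return symmetric nonnegative matrix, zero diagonal.
#' @export
omes_matrix <- function(msa_obj) {
  codes <- .msa_codes(msa_obj)
  .pair_matrix(ncol(codes), function(i, j) {
    ok <- codes[, i] > 0L & codes[, j] > 0L
    n <- sum(ok)
    if (n < 2L) return(0)
    obs <- table(codes[ok, i], codes[ok, j])
    exp_ <- outer(rowSums(obs), colSums(obs)) / n
    sum((obs - exp_)^2) / n
  })
}

#' Substitution-correlation coevolution score
#'
#' For every pair of sequences, each column yields the substitution-matrix
#' score of the two residues observed there; the coevolution score of
#' columns i and j is the Pearson correlation of these per-pair scores.
#' Columns with zero variance score 0.
#'
#' @param msa_obj an \code{msa} of depth >= 2.
#' @param submat 20x20 substitution matrix with amino-acid dimnames
#'   (default BLOSUM62).
#' @return symmetric matrix in [-1, 1], zero diagonal.
#' @export
mcbasc_matrix <- function(msa_obj, submat = NULL) {
  if (is.null(submat)) submat <- .blosum62()[AA_ALPHABET, AA_ALPHABET]
  codes <- .msa_codes(msa_obj)
  d <- nrow(codes)
  pairs <- utils::combn(d, 2)
  # per column: substitution score for every sequence pair, NA where gapped
  colscores <- apply(codes, 2, function(col) {
    a <- col[pairs[1, ]]; b <- col[pairs[2, ]]
    v <- rep(NA_real_, ncol(pairs))
    ok <- a > 0L & b > 0L
    v[ok] <- submat[cbind(a[ok], b[ok])]
    v
  })
  .pair_matrix(ncol(codes), function(i, j) {
    ok <- !is.na(colscores[, i]) & !is.na(colscores[, j])
    if (sum(ok) < 2L) return(0)
    si <- colscores[ok, i]; sj <- colscores[ok, j]
    if (stats::sd(si) == 0 || stats::sd(sj) == 0) return(0)
    stats::cor(si, sj)
  })
}

#' Average-product correction of a coevolution matrix
#'
#' out(i,j) = in(i,j) - mean_i * mean_j / mean_all, with means taken over
#' off-diagonal entries; the diagonal stays zero. An all-zero matrix is
#' returned unchanged.
#'
#' @param m symmetric matrix.
#' @return corrected symmetric matrix.
#' @export
apc_correction <- function(m) {
  stopifnot(isSymmetric(unname(m)))
  n <- nrow(m)
  if (n < 2L || all(m == 0)) return(m)
  off <- m
  diag(off) <- NA
  row_mean <- rowMeans(off, na.rm = TRUE)
  all_mean <- mean(off[!is.na(off)])
  if (all_mean == 0) return(m)
  out <- m - outer(row_mean, row_mean) / all_mean
  diag(out) <- 0
  out
}

#' Default registry of coevolution methods
#'
#' Named list of functions mapping an \code{msa} to a symmetric score
#' matrix. Users can add or replace entries to plug in further methods.
#'
#' @return named list of functions.
#' @export
default_correlation_methods <- function() {
  list(
    mi = mi_matrix,
    omes = omes_matrix,
    mcbasc = mcbasc_matrix,
    amic = function(m) apc_correction(mi_matrix(m))
  )
}

#' Consensus call of correlated alignment positions
#'
#' Each method flags its top \code{flag_fraction} of off-diagonal column
#' pairs by score (ties kept; zero or negative scores are never flagged).
#' A pair's consensus score is the number of methods flagging it. Because
#' the default decision threshold is calibrated against a reference panel
#' of \code{n_reference_methods} methods, the effective threshold for k
#' supplied methods is \code{threshold * k / n_reference_methods}. A
#' position is correlated when it belongs to at least one pair whose
#' consensus score reaches the effective threshold.
#'
#' @param method_matrices named list of symmetric score matrices of equal
#'   dimension (one per method).
#' @param flag_fraction fraction of pairs each method flags (default 0.01).
#' @param threshold consensus decision threshold on the reference-panel
#'   scale (default 3.5).
#' @param n_reference_methods size of the reference method panel the
#'   threshold refers to (default 7).
#' @return list with \code{consensus} (pair count matrix),
#'   \code{correlated_positions} (integer column indices),
#'   \code{effective_threshold} and per-method \code{flags} matrices.
#' @export
consensus_correlated <- function(method_matrices, flag_fraction = 0.01,
                                 threshold = 3.5, n_reference_methods = 7) {
  k <- length(method_matrices)
  if (k == 0L) stop("no correlation method matrices supplied")
  dims <- vapply(method_matrices, nrow, 0L)
  if (length(unique(dims)) != 1L) stop("method matrices differ in dimension")
  nc <- dims[[1]]
  ut <- upper.tri(matrix(0, nc, nc))
  n_pairs <- sum(ut)
  n_flag <- max(1L, ceiling(flag_fraction * n_pairs))
  flags <- lapply(method_matrices, function(m) {
    v <- m[ut]
    pos <- v[v > 0]
    f <- matrix(FALSE, nc, nc)
    if (length(pos)) {
      cutoff <- sort(pos, decreasing = TRUE)[min(n_flag, length(pos))]
      f[ut] <- v >= cutoff & v > 0
      f <- f | t(f)
    }
    f
  })
  consensus <- Reduce(`+`, lapply(flags, function(f) f * 1L))
  eff <- threshold * k / n_reference_methods
  hit <- consensus >= eff
  correlated <- sort(unique(c(row(hit)[hit], col(hit)[hit])))
  list(consensus = consensus, correlated_positions = as.integer(correlated),
       effective_threshold = eff, flags = flags)
}

#' Annotate an alignment with conservation and correlation calls
#'
#' Convenience wrapper: computes conservation scores and grades, runs the
#' registered coevolution methods and the consensus call, and maps column
#' indices to query positions.
#'
#' @param msa_obj an \code{msa}.
#' @param methods named list of coevolution methods
#'   (default \code{\link{default_correlation_methods}}).
#' @param window,window_weight conservation smoothing parameters.
#' @param flag_fraction,threshold,n_reference_methods consensus parameters
#'   (see \code{\link{consensus_correlated}}).
#' @return list with per-query-position \code{grades}, \code{scores},
#'   \code{correlated_positions} (query numbering) and the raw column-level
#'   results.
#' @export
annotate_msa <- function(msa_obj, methods = default_correlation_methods(),
                         window = 3, window_weight = 0.5,
                         flag_fraction = 0.01, threshold = 3.5,
                         n_reference_methods = 7) {
  scores <- jsd_conservation(msa_obj, window = window,
                             window_weight = window_weight)
  grades <- conservation_grades(scores)
  mats <- lapply(methods, function(f) f(msa_obj))
  cons <- consensus_correlated(mats, flag_fraction = flag_fraction,
                               threshold = threshold,
                               n_reference_methods = n_reference_methods)
  qcols <- which(!is.na(msa_obj$colmap))
  qpos <- msa_obj$colmap[qcols]
  list(
    scores = stats::setNames(scores[qcols], qpos),
    grades = stats::setNames(grades[qcols], qpos),
    correlated_positions =
      sort(msa_obj$colmap[intersect(cons$correlated_positions, qcols)]),
    column_scores = scores, column_grades = grades, consensus = cons
  )
}
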