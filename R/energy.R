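# Energy-evaluator contract, the deterministic built-in surrogate potential,
# and the staged free-energy threshold filters of the saturation and
# back-to-consensus branches. Convention throughout: kcal/mol, negative =
# stabilizing.

#' Construct an energy evaluator
#'
#' An evaluator bundles two capabilities: \code{single(mutation)} and
#' \code{pair(mutation_a, mutation_b)}, both returning a free-energy change
#' in kcal/mol (negative = stabilizing). Mutations are strings in the
#' package's notation (\code{\link{parse_mutation}}). Pair evaluation is
#' symmetrised and refuses two mutations at the same position.
#'
#' @param single function(mutation) -> numeric.
#' @param pair function(mutation_a, mutation_b) -> numeric; mutations are
#'   passed in canonical (position-sorted) order.
#' @param label free-text description.
#' @return an object of class \code{energy_evaluator}.
#' @export
energy_evaluator <- function(single, pair, label = "custom") {
  pair_wrapped <- function(mut_a, mut_b) {
    pa <- parse_mutation(mut_a)
    pb <- parse_mutation(mut_b)
    if (pa$chain == pb$chain && pa$pos == pb$pos)
      stop("pair evaluation refused: both mutations at position ",
           pa$chain, ":", pa$pos)
    if (pa$pos > pb$pos) { tmp <- mut_a; mut_a <- mut_b; mut_b <- tmp }
    pair(mut_a, mut_b)
  }
  obj <- list(single = single, pair = pair_wrapped, label = label)
  class(obj) <- "energy_evaluator"
  obj
}

#' @export
print.energy_evaluator <- function(x, ...) {
  cat("energy_evaluator:", x$label, "\n")
  invisible(x)
}

.contact_potential <- function(aa_a, aa_b) {
  # hydrophobicity-product contact potential: burial of mutually
  # hydrophobic residues is favourable. The 0.05 kcal/mol scale puts
  # per-contact energy differences near 1 kcal/mol, the order of
  # statistical contact potentials, so whole-protein saturation scans
  # spread with a standard deviation around 1 kcal/mol and a stabilizing
  # tail of roughly ten percent at the -1 kcal/mol threshold.
  -0.05 * KYTE_DOOLITTLE[[aa_a]] * KYTE_DOOLITTLE[[aa_b]]
}

# deterministic position/mutation-hashed pseudo-noise in [-1, 1]
.hash_noise <- function(seed, pos, code) {
  x <- sin(seed * 12.9898 + pos * 78.233 + code * 37.719) * 43758.5453
  2 * (x - floor(x)) - 1
}

#' Deterministic surrogate free-energy evaluator
#'
#' A desk-scale stand-in for force-field saturation mutagenesis: the
#' free-energy change of a mutation is the sum over neighbouring residues
#' (side-chain centroid proxy: C-beta, C-alpha for glycine, within
#' \code{contact_radius}) of the change in a hydrophobicity-product contact
#' potential, plus a seeded position-hashed noise term. Pair energies add a
#' coupling term when the two mutated residues are themselves in contact
#' and are exactly additive otherwise. Fully deterministic for a fixed
#' seed.
#'
#' @param structure a \code{structure_model}; mutation positions are
#'   matched against author residue numbers.
#' @param seed integer seed for the noise term.
#' @param noise_amplitude noise half-range in kcal/mol (default 0.2).
#' @param contact_radius neighbour cutoff in Angstrom (default 6.5).
#' @return an \code{energy_evaluator}.
#' @export
surrogate_evaluator <- function(structure, seed = 1, noise_amplitude = 0.2,
                                contact_radius = 6.5) {
  a <- structure$atoms
  rt <- residue_table(structure)
  # side-chain reference point: C-beta, falling back to C-alpha
  ref <- t(vapply(seq_len(nrow(rt)), function(i) {
    sel <- a$chain == rt$chain[i] & a$resno == rt$resno[i] &
      a$icode == rt$icode[i]
    cb <- which(sel & a$elety == "CB")
    if (!length(cb)) cb <- which(sel & a$elety == "CA")
    if (!length(cb)) cb <- which(sel)[1]
    c(a$x[cb[1]], a$y[cb[1]], a$z[cb[1]])
  }, numeric(3)))
  d <- as.matrix(stats::dist(ref))
  contact <- d <= contact_radius & upper.tri(d) | d <= contact_radius & lower.tri(d)

  find_res <- function(m) {
    i <- which(rt$chain == m$chain & rt$resno == m$pos)
    if (!length(i)) stop("mutation position not in structure: ",
                         m$chain, ":", m$pos)
    i[1]
  }
  single_raw <- function(mutation) {
    m <- parse_mutation(mutation, chains = structure$chains)
    i <- find_res(m)
    if (rt$aa[i] != m$wt)
      stop("wild-type mismatch at ", m$chain, ":", m$pos, ": structure has ",
           rt$aa[i], ", mutation says ", m$wt)
    nb <- which(contact[i, ])
    dE <- 0
    for (j in nb) {
      dE <- dE + .contact_potential(m$mut, rt$aa[j]) -
        .contact_potential(m$wt, rt$aa[j])
    }
    dE + noise_amplitude *
      .hash_noise(seed, m$pos, match(m$mut, AA_ALPHABET))
  }
  pair_raw <- function(mut_a, mut_b) {
    ma <- parse_mutation(mut_a, chains = structure$chains)
    mb <- parse_mutation(mut_b, chains = structure$chains)
    ia <- find_res(ma); ib <- find_res(mb)
    total <- single_raw(mut_a) + single_raw(mut_b)
    if (contact[ia, ib]) {
      total <- total + .contact_potential(ma$mut, mb$mut) -
        .contact_potential(ma$wt, mb$wt)
    }
    total
  }
  energy_evaluator(single_raw, pair_raw,
                   label = sprintf("surrogate(seed=%d)", seed))
}

#' Table-backed energy evaluator
#'
#' Wraps exported single and pair free-energy tables. A missing single
#' entry is an error; a missing pair entry falls back to additivity
#' (sum of the singles) and increments a warning counter retrievable with
#' \code{attr(evaluator, "fallbacks")()}.
#'
#' @param ddg_single a \code{\link{ddg_table}} of single-mutation values.
#' @param ddg_pairs optional named numeric vector of pair values keyed
#'   \code{"<mut_a>+<mut_b>"} with the two mutations sorted by position.
#' @return an \code{energy_evaluator}.
#' @export
table_evaluator <- function(ddg_single, ddg_pairs = NULL) {
  fallback_count <- 0L
  single <- function(mutation) {
    i <- match(mutation, names(ddg_single))
    if (is.na(i)) stop("no ddG entry for mutation: ", mutation)
    ddg_single[[i]]
  }
  pair <- function(mut_a, mut_b) {
    key <- paste(mut_a, mut_b, sep = "+")
    if (!is.null(ddg_pairs) && key %in% names(ddg_pairs))
      return(ddg_pairs[[key]])
    fallback_count <<- fallback_count + 1L
    single(mut_a) + single(mut_b)
  }
  ev <- energy_evaluator(single, pair,
                         label = paste0("table(",
                                        attr(ddg_single, "provenance"), ")"))
  attr(ev, "fallbacks") <- function() fallback_count
  ev
}

.safe_eval <- function(fun, ...) {
  tryCatch(fun(...), error = function(e) {
    warning(conditionMessage(e))
    NA_real_
  })
}

#' Two-stage free-energy threshold filter
#'
#' The staged cascade of the saturation branch: candidates are evaluated by
#' the first-stage (fast, coarse) evaluator and only survivors of its
#' threshold are forwarded to the second-stage evaluator; a candidate
#' survives when both thresholds are met (inclusive). Both energies are
#' recorded on the candidate table. Evaluation failures mark the candidate
#' unevaluated and excluded.
#'
#' @param candidates candidate data frame with a \code{mutation} column.
#' @param evaluator_stage1,evaluator_stage2 \code{energy_evaluator}s (may be
#'   identical).
#' @param stage1_threshold first-stage cutoff in kcal/mol (default -1.0).
#' @param stage2_threshold second-stage cutoff in kcal/mol (default -1.5).
#' @return the candidate table with columns \code{ddg_stage1},
#'   \code{ddg_stage2}, \code{energy_pass}, \code{energy_reason} added;
#'   survivors are the rows with \code{energy_pass} TRUE.
#' @export
energy_stage_filter <- function(candidates, evaluator_stage1,
                                evaluator_stage2,
                                stage1_threshold = -1.0,
                                stage2_threshold = -1.5) {
  n <- nrow(candidates)
  s1 <- rep(NA_real_, n); s2 <- rep(NA_real_, n)
  pass <- rep(FALSE, n); reason <- rep("", n)
  for (i in seq_len(n)) {
    s1[i] <- .safe_eval(evaluator_stage1$single, candidates$mutation[i])
    if (is.na(s1[i])) { reason[i] <- "unevaluated"; next }
    if (s1[i] > stage1_threshold) { reason[i] <- "stage1-threshold"; next }
    s2[i] <- .safe_eval(evaluator_stage2$single, candidates$mutation[i])
    if (is.na(s2[i])) { reason[i] <- "unevaluated"; next }
    if (s2[i] > stage2_threshold) { reason[i] <- "stage2-threshold"; next }
    pass[i] <- TRUE
  }
  candidates$ddg_stage1 <- s1
  candidates$ddg_stage2 <- s2
  candidates$energy_pass <- pass
  candidates$energy_reason <- reason
  candidates
}

#' Energy check of back-to-consensus candidates
#'
#' Consensus mutations are trusted on evolutionary grounds; the energy
#' check only removes clearly destabilizing ones (value above the
#' tolerance threshold, default +0.5 kcal/mol). Candidates that would also
#' pass the first-stage saturation threshold are additionally flagged
#' \code{energy_stabilizing}.
#'
#' @param candidates candidate data frame with a \code{mutation} column.
#' @param evaluator an \code{energy_evaluator}.
#' @param threshold tolerance cutoff in kcal/mol, inclusive (default +0.5).
#' @param stabilizing_threshold flag cutoff for "also energy-stabilizing"
#'   (default -1.0).
#' @return the candidate table with \code{ddg_consensus},
#'   \code{consensus_pass}, \code{energy_stabilizing} and
#'   \code{energy_reason} columns added.
#' @export
consensus_energy_filter <- function(candidates, evaluator, threshold = 0.5,
                                    stabilizing_threshold = -1.0) {
  n <- nrow(candidates)
  v <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    v[i] <- .safe_eval(evaluator$single, candidates$mutation[i])
  }
  candidates$ddg_consensus <- v
  candidates$consensus_pass <- !is.na(v) & v <= threshold
  candidates$energy_stabilizing <- !is.na(v) & v <= stabilizing_threshold
  candidates$energy_reason <- ifelse(is.na(v), "unevaluated",
                                     ifelse(candidates$consensus_pass, "",
                                            "consensus-threshold"))
  candidates
}
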