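# Candidate single-point mutations (saturation, back-to-consensus,
# ancestral) and the position-level and mutation-level filter cascades that
# define the low-risk and high-risk scenarios.

.candidate_frame <- function(chain, pos, qpos, wt, mut, source) {
  data.frame(
    mutation = mutation_id(wt, pos, mut),
    chain = chain, pos = as.integer(pos), qpos = as.integer(qpos),
    wt = wt, mut = mut, source = source,
    filter_reason = character(max(length(pos), length(mut))),
    stringsAsFactors = FALSE
  )
}

#' Saturation-mutagenesis candidates
#'
#' All 19 non-wild-type substitutions at each requested position.
#'
#' @param query_sequence query amino-acid sequence (string).
#' @param positions query positions (1-based indices into the sequence);
#'   default all.
#' @param chain chain identifier for the candidates.
#' @param numbering author residue number per query position (defaults to
#'   the query index).
#' @return candidate data frame (mutation, chain, pos, qpos, wt, mut,
#'   source).
#' @export
saturation_candidates <- function(query_sequence, positions = NULL,
                                  chain = "A", numbering = NULL) {
  qchars <- strsplit(query_sequence, "")[[1]]
  if (is.null(positions)) positions <- seq_along(qchars)
  if (any(positions < 1 | positions > length(qchars)))
    stop("position out of sequence range")
  if (is.null(numbering)) numbering <- seq_along(qchars)
  rows <- lapply(positions, function(p) {
    wt <- qchars[p]
    if (!is_standard_aa(wt))
      stop("cannot saturate position ", p, ": wild type '", wt,
           "' is not a standard amino acid")
    muts <- setdiff(AA_ALPHABET, wt)
    .candidate_frame(chain, numbering[p], p, wt, muts, "saturation")
  })
  do.call(rbind, rows)
}

#' Back-to-consensus candidates
#'
#' For each query position, the most frequent residue c of the alignment
#' column is a candidate replacement when it differs from the wild type
#' and either (majority rule) its frequency is at least 0.50, or (ratio
#' rule) its frequency is at least 0.40 and at least five times the
#' wild-type residue's frequency. At most one candidate per position.
#' Column frequencies exclude gaps from the denominator by default.
#'
#' @param msa_obj an \code{msa}.
#' @param majority_freq majority-rule frequency threshold (default 0.50).
#' @param ratio_freq ratio-rule frequency threshold (default 0.40).
#' @param ratio_factor required consensus/wild-type frequency ratio
#'   (default 5).
#' @param count_gaps include gaps in the frequency denominator
#'   (default FALSE).
#' @param chain chain identifier for the candidates.
#' @param numbering author residue number per query position.
#' @return candidate data frame with sources \code{consensus-majority} /
#'   \code{consensus-ratio} and columns \code{consensus_freq},
#'   \code{wt_freq}.
#' @export
back_to_consensus <- function(msa_obj, majority_freq = 0.50,
                              ratio_freq = 0.40, ratio_factor = 5,
                              count_gaps = FALSE, chain = "A",
                              numbering = NULL) {
  prof <- column_profile(msa_obj)
  cols <- which(!is.na(msa_obj$colmap))
  if (is.null(numbering)) numbering <- seq_len(nchar(msa_obj$query_seq))
  qchars <- strsplit(msa_obj$query_seq, "")[[1]]
  rows <- list()
  for (cc in cols) {
    qpos <- msa_obj$colmap[cc]
    wt <- qchars[qpos]
    counts <- prof$counts[, cc]
    denom <- if (count_gaps) prof$depth else sum(counts)
    if (denom == 0) next
    freqs <- counts / denom
    cons <- AA_ALPHABET[which.max(freqs)]  # ties: alphabetically first
    if (cons == wt) next
    f_cons <- freqs[[cons]]
    f_wt <- if (wt %in% AA_ALPHABET) freqs[[wt]] else 0
    src <- if (f_cons >= majority_freq) {
      "consensus-majority"
    } else if (f_cons >= ratio_freq && f_cons >= ratio_factor * f_wt) {
      "consensus-ratio"
    } else {
      next
    }
    row <- .candidate_frame(chain, numbering[qpos], qpos, wt, cons, src)
    row$consensus_freq <- f_cons
    row$wt_freq <- f_wt
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows)) {
    out <- .candidate_frame(character(0), integer(0), integer(0),
                            character(0), character(0), character(0))
    out$consensus_freq <- numeric(0)
    out$wt_freq <- numeric(0)
    return(out)
  }
  do.call(rbind, rows)
}

#' Substitutions between the query and ancestral sequences
#'
#' Each ancestral sequence is globally aligned to the query (BLOSUM62,
#' affine gaps 10/0.5); residues differing at aligned non-gap columns are
#' reported as mutations in query numbering. Insertions and deletions are
#' ignored.
#'
#' @param query query sequence (string).
#' @param ancestral_sequences named character vector of ancestral-node
#'   sequences (root-ward internal nodes of the query lineage).
#' @return named list (one element per node) of mutation strings.
#' @export
ancestral_substitutions <- function(query, ancestral_sequences) {
  if (length(ancestral_sequences) == 0L) stop("no ancestral sequences")
  if (is.null(names(ancestral_sequences)))
    names(ancestral_sequences) <- paste0("node", seq_along(ancestral_sequences))
  out <- list()
  for (nm in names(ancestral_sequences)) {
    anc <- ancestral_sequences[[nm]]
    if (!nzchar(anc)) {
      warning("skipping empty ancestral sequence: ", nm)
      next
    }
    aln <- align_global(query, anc)
    ca <- strsplit(aln$a, "")[[1]]
    cb <- strsplit(aln$b, "")[[1]]
    qpos <- cumsum(ca != "-")
    subst <- ca != "-" & cb != "-" & ca != cb &
      is_standard_aa(ca) & is_standard_aa(cb)
    out[[nm]] <- mutation_id(ca[subst], qpos[subst], cb[subst])
  }
  out
}

#' Keep ancestral substitutions recurring across nodes
#'
#' Mutations close to the root are numerous and unreliable; only those
#' present in at least \code{min_nodes} distinct ancestral nodes are kept.
#'
#' @param per_node_lists output of \code{\link{ancestral_substitutions}}.
#' @param min_nodes minimal number of supporting nodes (default 2).
#' @param chain chain identifier for the candidates.
#' @param numbering author residue number per query position.
#' @return candidate data frame with source \code{ancestral} and a
#'   \code{n_nodes} support column.
#' @export
recurrent_ancestral_filter <- function(per_node_lists, min_nodes = 2,
                                       chain = "A", numbering = NULL) {
  all_muts <- unlist(lapply(per_node_lists, unique), use.names = FALSE)
  counts <- table(all_muts)
  keep <- names(counts)[counts >= min_nodes]
  if (!length(keep)) {
    out <- .candidate_frame(character(0), integer(0), integer(0),
                            character(0), character(0), character(0))
    out$n_nodes <- integer(0)
    return(out)
  }
  parsed <- lapply(keep, parse_mutation, chains = chain)
  qpos <- vapply(parsed, function(m) m$pos, 0L)
  if (is.null(numbering)) numbering <- seq_len(max(qpos))
  out <- .candidate_frame(
    chain, numbering[qpos], qpos,
    vapply(parsed, function(m) m$wt, ""),
    vapply(parsed, function(m) m$mut, ""),
    "ancestral"
  )
  out$n_nodes <- as.integer(counts[keep])
  out <- out[order(out$pos, out$mut), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---------------------------------------------------------------------------
# Filter policies and cascades

#' Filter policy for a design scenario
#'
#' Position-level filters (essential, conserved, correlated residues) are
#' always enabled. The low-risk policy additionally enables the
#' mutation-level filters (alignment presence and charge change on the
#' surface); the high-risk policy disables exactly those two.
#'
#' @param risk \code{"low"} or \code{"high"}.
#' @param conserved_grade_max grade at or below which a position counts as
#'   conserved and is excluded (default 4).
#' @return list of class \code{filter_policy}.
#' @export
filter_policy <- function(risk = c("low", "high"), conserved_grade_max = 4) {
  risk <- match.arg(risk)
  out <- list(risk = risk,
              conserved_grade_max = conserved_grade_max,
              msa_presence = risk == "low",
              charge_surface = risk == "low")
  class(out) <- "filter_policy"
  out
}

#' Position-level safety filters
#'
#' Rejects candidates at essential residues, at conserved positions
#' (grade at or below the policy cutoff) and at correlated positions.
#' Applied in both risk modes; the first failing filter's reason is
#' recorded (evaluation order: essential, conserved, correlated).
#'
#' @param candidates candidate data frame.
#' @param essential_positions integer vector of essential author positions
#'   (may be empty).
#' @param grades named integer vector: conservation grade per author
#'   position (names are positions).
#' @param correlated_positions integer vector of correlated author
#'   positions.
#' @param policy a \code{\link{filter_policy}}.
#' @return candidates with \code{essential}, \code{grade},
#'   \code{correlated}, \code{position_pass} columns and updated
#'   \code{filter_reason}.
#' @export
apply_position_filters <- function(candidates, essential_positions, grades,
                                   correlated_positions, policy) {
  g <- grades[as.character(candidates$pos)]
  if (anyNA(g))
    stop("missing conservation annotation for position(s): ",
         paste(unique(candidates$pos[is.na(g)]), collapse = ", "))
  candidates$essential <- candidates$pos %in% essential_positions
  candidates$grade <- as.integer(g)
  candidates$correlated <- candidates$pos %in% correlated_positions
  reason <- candidates$filter_reason
  fail_ess <- candidates$essential & reason == ""
  reason[fail_ess] <- "essential"
  fail_cons <- candidates$grade <= policy$conserved_grade_max & reason == ""
  reason[fail_cons] <- "conserved"
  fail_cor <- candidates$correlated & reason == ""
  reason[fail_cor] <- "correlated"
  candidates$filter_reason <- reason
  candidates$position_pass <- reason == ""
  candidates
}

#' Mutation-level safety filters
#'
#' In the low-risk policy a candidate is rejected when (a) its target
#' residue never occurs in its alignment column, or (b) it changes the
#' charge class and its position is on the protein surface. The high-risk
#' policy skips both checks (annotations are still recorded). Charge
#' classes: K/R positive, D/E negative, all else neutral.
#'
#' @param candidates candidate data frame (with \code{qpos} query indices).
#' @param msa_obj an \code{msa} for column lookups.
#' @param surface_keys residue keys on the surface
#'   (\code{\link{surface_mask}}).
#' @param policy a \code{\link{filter_policy}}.
#' @return candidates with \code{msa_presence}, \code{charge_change},
#'   \code{surface}, \code{mutation_pass} columns and updated
#'   \code{filter_reason}.
#' @export
apply_mutation_filters <- function(candidates, msa_obj, surface_keys,
                                   policy) {
  n <- nrow(candidates)
  qcol <- match(candidates$qpos, msa_obj$colmap)
  presence <- vapply(seq_len(n), function(i) {
    if (is.na(qcol[i])) return(NA)
    candidates$mut[i] %in% msa_obj$mat[, qcol[i]]
  }, logical(1))
  charge_change <- aa_charge_class(candidates$wt) !=
    aa_charge_class(candidates$mut)
  on_surface <- paste0(candidates$chain, ":", candidates$pos) %in% surface_keys
  candidates$msa_presence <- presence
  candidates$charge_change <- charge_change
  candidates$surface <- on_surface
  reason <- candidates$filter_reason
  if (policy$msa_presence) {
    fail <- !is.na(presence) & !presence & reason == ""
    reason[fail] <- "msa-presence"
  }
  if (policy$charge_surface) {
    fail <- charge_change & on_surface & reason == ""
    reason[fail] <- "charge-surface"
  }
  candidates$filter_reason <- reason
  candidates$mutation_pass <- reason == ""
  candidates
}
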