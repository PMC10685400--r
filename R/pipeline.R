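# End-to-end automated design: annotate the target protein, generate and
# filter candidate single-point mutations in three branches (saturation
# energies, back-to-consensus, ancestral) and assemble multiple-point
# designs per scenario via the pair-energy graph and maximal-clique search.

#' Read an essential-residue list
#'
#' One residue per line as \code{<chain>/<position>} (or bare position,
#' chain "A"); blank lines and \code{#} comments ignored.
#'
#' @param path input file.
#' @return data frame with \code{chain} and \code{pos}.
#' @export
read_essential <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  m <- regmatches(lines, regexec("^(?:([A-Za-z0-9])/)?([0-9]+)$", lines))
  bad <- which(vapply(m, length, 0L) == 0L)
  if (length(bad)) stop("unparseable essential-residue line: ", lines[bad[1]])
  data.frame(
    chain = vapply(m, function(x) if (x[2] == "") "A" else x[2], ""),
    pos = as.integer(vapply(m, `[`, "", 3)), stringsAsFactors = FALSE)
}

#' Automated design of stabilizing multiple-point mutants
#'
#' The full protocol: the target protein (structure + homolog alignment)
#' is annotated with conservation grades, consensus-correlated positions,
#' solvent accessibility and B-factor flexibility; candidate single-point
#' mutations are generated by saturation mutagenesis (two-stage
#' free-energy thresholds), back-to-consensus rules and, when ancestral
#' sequences are given, recurrent ancestral substitutions; safety filters
#' define low- and high-risk pools; and per scenario the non-antagonistic
#' pair graph is searched for the most stabilizing maximal clique.
#'
#' @param structure a \code{structure_model} of the target protein.
#' @param msa_obj an \code{msa} whose query row matches the selected
#'   chain's sequence.
#' @param evaluator_stage1 first-stage (saturation) energy evaluator;
#'   default a \code{\link{surrogate_evaluator}} on \code{structure}.
#' @param evaluator_stage2 second-stage evaluator; defaults to
#'   \code{evaluator_stage1}.
#' @param ancestors optional named character vector of ancestral
#'   sequences.
#' @param essential integer vector of essential author positions.
#' @param chain chain to design on (default first chain).
#' @param seed seed for the default surrogate evaluator.
#' @param saturation_positions \code{"all"} or \code{"flexible"} (restrict
#'   saturation to the \code{flexible_top_n} most flexible residues).
#' @param flexible_top_n number of flexible residues when
#'   \code{saturation_positions = "flexible"}.
#' @param stage1_threshold,stage2_threshold,consensus_threshold
#'   free-energy cutoffs in kcal/mol (defaults -1.0, -1.5, +0.5).
#' @param radius pair-evaluation radius in Angstrom (default 10).
#' @param rel_sasa_threshold surface cutoff on relative SASA (default
#'   0.25).
#' @param conserved_grade_max conservation-grade cutoff (default 4).
#' @param min_ancestral_nodes recurrence threshold for ancestral
#'   substitutions (default 2).
#' @param correlation_methods named list of coevolution methods.
#' @return an object of class \code{stability_designs}: list with
#'   \code{designs} (per-scenario \code{stability_design}s),
#'   \code{candidates} (annotated saturation table),
#'   \code{consensus_candidates}, \code{ancestral_candidates},
#'   \code{annotations}, \code{sasa}, \code{flexibility}, \code{query}
#'   and \code{params}.
#' @export
design_stability <- function(structure, msa_obj,
                             evaluator_stage1 = NULL,
                             evaluator_stage2 = NULL,
                             ancestors = NULL,
                             essential = integer(0),
                             chain = structure$chains[1],
                             seed = 1,
                             saturation_positions = c("all", "flexible"),
                             flexible_top_n = 10,
                             stage1_threshold = -1.0,
                             stage2_threshold = -1.5,
                             consensus_threshold = 0.5,
                             radius = 10.0,
                             rel_sasa_threshold = 0.25,
                             conserved_grade_max = 4,
                             min_ancestral_nodes = 2,
                             correlation_methods =
                               default_correlation_methods()) {
  saturation_positions <- match.arg(saturation_positions)
  cs <- chain_sequence(structure, chain)
  if (cs$sequence != msa_obj$query_seq)
    stop("alignment query sequence does not match the structure's chain ",
         chain, " sequence")
  numbering <- cs$resno
  if (is.null(evaluator_stage1))
    evaluator_stage1 <- surrogate_evaluator(structure, seed = seed)
  if (is.null(evaluator_stage2)) evaluator_stage2 <- evaluator_stage1

  # --- annotation
  ann <- annotate_msa(msa_obj, methods = correlation_methods)
  grades <- stats::setNames(as.integer(ann$grades),
                            numbering[as.integer(names(ann$grades))])
  correlated <- numbering[ann$correlated_positions]
  sasa <- shrake_rupley_sasa(structure)
  surface <- surface_mask(sasa, rel_sasa_threshold)
  flex <- residue_avg_bfactor(structure)

  policy_low <- filter_policy("low", conserved_grade_max)
  policy_high <- filter_policy("high", conserved_grade_max)

  # --- saturation branch
  sat_pos <- if (saturation_positions == "flexible") {
    fx <- flexible_positions(flex[flex$chain == chain, , drop = FALSE],
                             flexible_top_n)
    match(fx$resno, numbering)
  } else {
    seq_along(numbering)
  }
  cand <- saturation_candidates(cs$sequence, sat_pos, chain, numbering)
  cand <- apply_position_filters(cand, essential, grades, correlated,
                                 policy_low)
  cand_low <- apply_mutation_filters(cand, msa_obj, surface, policy_low)
  cand_high <- apply_mutation_filters(cand, msa_obj, surface, policy_high)
  eval_pool <- function(tab) {
    ok <- tab$filter_reason == ""
    scored <- energy_stage_filter(tab[ok, , drop = FALSE],
                                  evaluator_stage1, evaluator_stage2,
                                  stage1_threshold, stage2_threshold)
    tab$ddg_stage1 <- NA_real_; tab$ddg_stage2 <- NA_real_
    tab$energy_pass <- FALSE
    tab[ok, names(scored)] <- scored
    tab
  }
  cand_low <- eval_pool(cand_low)
  cand_high <- eval_pool(cand_high)

  pool_of <- function(tab) {
    p <- tab[tab$filter_reason == "" & tab$energy_pass, , drop = FALSE]
    p$ddg <- p$ddg_stage1
    rownames(p) <- NULL
    p
  }
  pool_low <- pool_of(cand_low)
  pool_high <- pool_of(cand_high)

  # --- evolution branch (back-to-consensus)
  cons <- back_to_consensus(msa_obj, chain = chain, numbering = numbering)
  if (nrow(cons)) {
    cons <- apply_position_filters(cons, essential, grades, correlated,
                                   policy_low)
    cons <- consensus_energy_filter(cons[cons$position_pass, , drop = FALSE],
                                    evaluator_stage1, consensus_threshold,
                                    stage1_threshold)
  }
  pool_evo <- if (nrow(cons)) {
    p <- cons[cons$consensus_pass, , drop = FALSE]
    p$ddg <- p$ddg_consensus
    rownames(p) <- NULL
    p
  } else {
    cons
  }

  # --- clique designs
  clique_design <- function(pool, scenario) {
    if (nrow(pool) == 0L)
      return(stability_design(scenario, pool, 0, cs$sequence))
    pairs <- build_pair_set(pool, structure, evaluator_stage1, radius)
    g <- build_design_graph(pool, pairs)
    d <- select_design(enumerate_maximal_cliques(g), pool, scenario)
    d$sequence <- mutant_sequence(cs$sequence, d)
    d$graph <- g
    d
  }
  designs <- list(
    "energy-low" = clique_design(pool_low, "energy-low"),
    "energy-high" = clique_design(pool_high, "energy-high"),
    "evolution" = clique_design(pool_evo, "evolution")
  )
  for (risk in c("low", "high")) {
    sc <- paste0("combined-", risk)
    base <- designs[[paste0("energy-", risk)]]
    d <- combined_design(base, designs[["evolution"]], structure,
                         evaluator_stage1, radius, sc,
                         prior_pairs = rbind(
                           if (!is.null(base$graph)) base$graph$pairs,
                           if (!is.null(designs[["evolution"]]$graph))
                             designs[["evolution"]]$graph$pairs))
    d$sequence <- mutant_sequence(cs$sequence, d)
    designs[[sc]] <- d
  }

  # --- ancestral branch (reported single-point list, no clique search)
  anc_cand <- NULL
  if (!is.null(ancestors) && length(ancestors)) {
    per_node <- ancestral_substitutions(msa_obj$query_seq, ancestors)
    anc_cand <- recurrent_ancestral_filter(per_node, min_ancestral_nodes,
                                           chain, numbering)
    if (nrow(anc_cand)) {
      anc_cand <- apply_position_filters(anc_cand, essential, grades,
                                         correlated, policy_low)
      keep <- anc_cand[anc_cand$position_pass, , drop = FALSE]
      keep$ddg <- vapply(keep$mutation, function(m)
        .safe_eval(evaluator_stage1$single, m), 0)
      rownames(keep) <- NULL
      d <- stability_design("ancestral", keep, sum(keep$ddg, na.rm = TRUE))
      d$sequence <- mutant_sequence(cs$sequence, d)
      designs[["ancestral"]] <- d
    }
  }

  out <- list(
    designs = designs,
    candidates = list(low = cand_low, high = cand_high),
    consensus_candidates = cons,
    ancestral_candidates = anc_cand,
    annotations = list(grades = grades, correlated = correlated,
                       scores = ann$scores, consensus = ann$consensus),
    sasa = sasa, surface = surface, flexibility = flex,
    query = list(sequence = cs$sequence, numbering = numbering,
                 chain = chain),
    params = list(stage1_threshold = stage1_threshold,
                  stage2_threshold = stage2_threshold,
                  consensus_threshold = consensus_threshold,
                  radius = radius,
                  rel_sasa_threshold = rel_sasa_threshold,
                  conserved_grade_max = conserved_grade_max,
                  seed = seed)
  )
  class(out) <- "stability_designs"
  out
}

#' @export
print.stability_designs <- function(x, ...) {
  cat("stability_designs over", nchar(x$query$sequence),
      "residues (chain", paste0(x$query$chain, ")"), "\n")
  for (d in x$designs) {
    cat(sprintf("  %-13s %2d mutation(s)  total ddG %7.3f  %s\n",
                d$scenario, nrow(d$mutations), d$total_score,
                if (nrow(d$mutations))
                  paste(d$mutations$mutation, collapse = " ") else "-"))
  }
  invisible(x)
}

#' @export
summary.stability_designs <- function(object, ...) {
  cl <- object$candidates$low
  ch <- object$candidates$high
  tab <- data.frame(
    scenario = vapply(object$designs, function(d) d$scenario, ""),
    n_mutations = vapply(object$designs, function(d)
      nrow(d$mutations), 0L),
    total_ddg = vapply(object$designs, function(d) d$total_score, 0),
    row.names = NULL
  )
  out <- list(
    designs = tab,
    n_candidates = nrow(cl),
    survivors_low = sum(cl$filter_reason == "" & cl$energy_pass),
    survivors_high = sum(ch$filter_reason == "" & ch$energy_pass),
    rejection_reasons = table(cl$filter_reason[cl$filter_reason != ""]),
    n_conserved_positions =
      sum(object$annotations$grades <= object$params$conserved_grade_max),
    n_correlated_positions = length(object$annotations$correlated),
    n_surface = length(object$surface)
  )
  class(out) <- "summary.stability_designs"
  out
}

#' @export
print.summary.stability_designs <- function(x, ...) {
  cat("Candidate mutations:", x$n_candidates,
      "| low-risk survivors:", x$survivors_low,
      "| high-risk survivors:", x$survivors_high, "\n")
  cat("Conserved positions:", x$n_conserved_positions,
      "| correlated:", x$n_correlated_positions,
      "| surface residues:", x$n_surface, "\n")
  cat("Rejections:\n")
  print(x$rejection_reasons)
  cat("Designs:\n")
  print(x$designs, row.names = FALSE)
  invisible(x)
}

#' Plot design scores and the candidate energy landscape
#'
#' Left panel: total predicted stabilisation per design scenario. Right
#' panel: first-stage free-energy distribution of all evaluated
#' candidates with the stage thresholds marked.
#'
#' @param x a \code{stability_designs}.
#' @param ... ignored.
#' @return \code{x}, invisibly.
#' @export
plot.stability_designs <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2), mar = c(7, 4, 2, 1))
  on.exit(graphics::par(op))
  sc <- vapply(x$designs, function(d) d$total_score, 0)
  graphics::barplot(sc, names.arg = names(x$designs), las = 2,
                    ylab = "total ddG [kcal/mol]", main = "designs",
                    col = ifelse(sc <= 0, "steelblue", "firebrick"))
  dd <- x$candidates$low$ddg_stage1
  dd <- dd[!is.na(dd)]
  if (length(dd)) {
    graphics::hist(dd, breaks = 30, main = "candidate ddG (stage 1)",
                   xlab = "ddG [kcal/mol]", col = "grey80")
    graphics::abline(v = x$params$stage1_threshold, lty = 2, col = "red")
  }
  invisible(x)
}
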