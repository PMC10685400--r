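# Multiple-point design: pair-energy computation under the 10 A radius rule,
# antagonistic-edge removal, Bron-Kerbosch maximal-clique enumeration and
# selection of the most stabilizing clique per scenario.

#' Pair free energies for a set of accepted single mutations
#'
#' Every unordered pair of mutations at distinct positions gets a pair
#' free-energy value: evaluated by the pair evaluator when the wild-type
#' residues lie within \code{radius} (minimal heavy-atom distance), and
#' taken as exactly additive (sum of the singles) beyond it. Pairs at one
#' position are never generated; evaluator failures mark the pair
#' unevaluated (its edge is later dropped).
#'
#' @param singles data frame of accepted single mutations with columns
#'   \code{mutation}, \code{chain}, \code{pos}, \code{ddg}.
#' @param structure a \code{structure_model} (for distances); with
#'   \code{NULL} no distances are available and every pair is evaluated by
#'   the evaluator.
#' @param evaluator an \code{energy_evaluator}.
#' @param radius pair-evaluation radius in Angstrom (default 10).
#' @return data frame with columns \code{mut_a}, \code{mut_b},
#'   \code{distance}, \code{ddg_pair}, \code{additive}, \code{evaluated}.
#' @export
build_pair_set <- function(singles, structure, evaluator, radius = 10.0) {
  n <- nrow(singles)
  rows <- list()
  if (n >= 2L) {
    dm <- NULL
    keys <- paste0(singles$chain, ":", singles$pos)
    if (!is.null(structure)) dm <- distance_map(structure, unique(keys))
    for (i in seq_len(n - 1L)) {
      for (j in seq(i + 1L, n)) {
        if (singles$chain[i] == singles$chain[j] &&
            singles$pos[i] == singles$pos[j]) next
        d <- if (is.null(dm)) NA_real_ else dm[keys[i], keys[j]]
        if (is.na(d) || d <= radius) {
          v <- .safe_eval(evaluator$pair, singles$mutation[i],
                          singles$mutation[j])
          rows[[length(rows) + 1L]] <- data.frame(
            mut_a = singles$mutation[i], mut_b = singles$mutation[j],
            distance = d, ddg_pair = v, additive = FALSE,
            evaluated = !is.na(v), stringsAsFactors = FALSE)
        } else {
          rows[[length(rows) + 1L]] <- data.frame(
            mut_a = singles$mutation[i], mut_b = singles$mutation[j],
            distance = d, ddg_pair = singles$ddg[i] + singles$ddg[j],
            additive = TRUE, evaluated = TRUE, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(mut_a = character(0), mut_b = character(0),
                      distance = numeric(0), ddg_pair = numeric(0),
                      additive = logical(0), evaluated = logical(0)))
  }
  do.call(rbind, rows)
}

#' Build the mutation-compatibility graph
#'
#' Nodes are accepted single mutations weighted by their free-energy
#' change; an edge between two mutations is retained only when the pair is
#' non-antagonistic: its pair value is at or below the better (more
#' negative) of the two singles. Unevaluated pairs and same-position pairs
#' never produce edges.
#'
#' @param singles data frame with \code{mutation}, \code{chain},
#'   \code{pos}, \code{ddg}.
#' @param pair_energies data frame from \code{\link{build_pair_set}}.
#' @return object of class \code{design_graph}: list with \code{nodes},
#'   \code{adj} (logical adjacency matrix) and \code{pairs}.
#' @export
build_design_graph <- function(singles, pair_energies) {
  n <- nrow(singles)
  adj <- matrix(FALSE, n, n,
                dimnames = list(singles$mutation, singles$mutation))
  ddg <- stats::setNames(singles$ddg, singles$mutation)
  for (k in seq_len(nrow(pair_energies))) {
    pe <- pair_energies[k, ]
    if (!pe$evaluated) next
    if (!(pe$mut_a %in% singles$mutation) ||
        !(pe$mut_b %in% singles$mutation))
      stop("pair references unknown single mutation: ",
           pe$mut_a, "+", pe$mut_b)
    if (pe$ddg_pair <= min(ddg[[pe$mut_a]], ddg[[pe$mut_b]])) {
      adj[pe$mut_a, pe$mut_b] <- TRUE
      adj[pe$mut_b, pe$mut_a] <- TRUE
    }
  }
  obj <- list(nodes = singles, adj = adj, pairs = pair_energies)
  class(obj) <- "design_graph"
  obj
}

#' @export
print.design_graph <- function(x, ...) {
  cat("design_graph:", nrow(x$nodes), "mutations,",
      sum(x$adj[upper.tri(x$adj)]), "compatible pairs\n")
  invisible(x)
}

#' Enumerate all maximal cliques (Bron-Kerbosch with pivoting)
#'
#' @param graph a \code{design_graph} or a logical/0-1 adjacency matrix.
#' @return list of integer vectors (node indices), each sorted, the list
#'   ordered lexicographically. Isolated nodes yield singleton cliques.
#' @export
enumerate_maximal_cliques <- function(graph) {
  adj <- if (inherits(graph, "design_graph")) graph$adj else graph != 0
  n <- nrow(adj)
  if (n == 0L) return(list())
  nbrs <- lapply(seq_len(n), function(i) which(adj[i, ]))
  cliques <- list()
  bk <- function(r, p, x) {
    if (!length(p) && !length(x)) {
      cliques[[length(cliques) + 1L]] <<- sort(r)
      return(invisible())
    }
    # pivot: vertex of P union X with most neighbours in P
    px <- c(p, x)
    deg <- vapply(px, function(u) length(intersect(p, nbrs[[u]])), 0L)
    u <- px[which.max(deg)]
    for (v in setdiff(p, nbrs[[u]])) {
      bk(c(r, v), intersect(p, nbrs[[v]]), intersect(x, nbrs[[v]]))
      p <- setdiff(p, v)
      x <- c(x, v)
    }
  }
  bk(integer(0), seq_len(n), integer(0))
  ord <- order(vapply(cliques, function(cl) {
    paste(sprintf("%06d", cl), collapse = " ")
  }, ""))
  cliques[ord]
}

# lexicographic comparison key of a clique by member positions
.clique_pos_key <- function(clique_idx, singles) {
  paste(sprintf("%06d", sort(singles$pos[clique_idx])), collapse = " ")
}

#' Select the most stabilizing clique as a design
#'
#' The clique minimising the sum of its members' single free-energy
#' changes wins (pair values decide only edge existence); ties prefer the
#' larger clique, remaining ties the lexicographically smallest position
#' list. An empty clique list yields an empty (wild-type) design.
#'
#' @param cliques list of integer node-index vectors
#'   (\code{\link{enumerate_maximal_cliques}}).
#' @param singles node table of the graph (with \code{ddg}).
#' @param scenario scenario label for the design.
#' @return object of class \code{stability_design}: list with
#'   \code{scenario}, \code{mutations} (data frame), \code{total_score}
#'   and \code{sequence} (NA until \code{\link{mutant_sequence}}).
#' @export
select_design <- function(cliques, singles, scenario = "energy-low") {
  if (!length(cliques)) {
    return(stability_design(scenario,
                            singles[integer(0), , drop = FALSE], 0))
  }
  scores <- vapply(cliques, function(cl) sum(singles$ddg[cl]), 0)
  sizes <- lengths(cliques)
  keys <- vapply(cliques, .clique_pos_key, "", singles = singles)
  best <- order(scores, -sizes, keys)[1]
  cl <- cliques[[best]]
  mt <- singles[cl, , drop = FALSE]
  mt <- mt[order(mt$pos), , drop = FALSE]
  rownames(mt) <- NULL
  stability_design(scenario, mt, scores[best])
}

#' Construct a stability design object
#'
#' @param scenario scenario label (e.g. \code{"energy-low"},
#'   \code{"evolution"}, \code{"combined-high"}, \code{"ancestral"}).
#' @param mutations data frame of member mutations (needs \code{mutation},
#'   \code{chain}, \code{pos}, \code{ddg}; \code{wt}/\code{mut}/\code{qpos}
#'   used where available).
#' @param total_score sum of the member single free-energy changes.
#' @param sequence mutant sequence (optional).
#' @return object of class \code{stability_design}.
#' @export
stability_design <- function(scenario, mutations, total_score,
                             sequence = NA_character_) {
  if (anyDuplicated(paste(mutations$chain, mutations$pos)))
    stop("design contains two mutations at one position")
  obj <- list(scenario = scenario, mutations = mutations,
              total_score = total_score, sequence = sequence)
  class(obj) <- "stability_design"
  obj
}

#' @export
print.stability_design <- function(x, ...) {
  cat(sprintf("stability_design [%s]: %d mutation(s), total ddG %.3f kcal/mol\n",
              x$scenario, nrow(x$mutations), x$total_score))
  if (nrow(x$mutations))
    cat(" ", paste(x$mutations$mutation, collapse = " "), "\n")
  invisible(x)
}

#' Combined design from two mutation pools
#'
#' Union of two designs' mutations (same-position conflicts keep the more
#' stabilizing single), pair energies recomputed under the radius rule
#' (reusing any supplied prior pair values), antagonistic edges removed,
#' cliques re-enumerated and the best clique selected.
#'
#' @param design_a,design_b \code{stability_design}s to combine.
#' @param structure a \code{structure_model}.
#' @param evaluator an \code{energy_evaluator}.
#' @param radius pair-evaluation radius in Angstrom (default 10).
#' @param scenario label for the combined design.
#' @param prior_pairs optional pair data frame whose values are reused for
#'   pairs already evaluated.
#' @return a \code{stability_design}.
#' @export
combined_design <- function(design_a, design_b, structure, evaluator,
                            radius = 10.0, scenario = "combined-low",
                            prior_pairs = NULL) {
  core <- function(mt) {
    if (!("qpos" %in% names(mt))) mt$qpos <- mt$pos
    if (!("source" %in% names(mt))) mt$source <- rep("user", nrow(mt))
    if (!("ddg" %in% names(mt))) mt$ddg <- rep(NA_real_, nrow(mt))
    mt[, c("mutation", "chain", "pos", "qpos", "wt", "mut", "source", "ddg"),
       drop = FALSE]
  }
  pool <- rbind(core(design_a$mutations), core(design_b$mutations))
  if (nrow(pool) == 0L)
    return(stability_design(scenario, pool, 0))
  # same-position conflicts: keep the more stabilizing single
  pool <- pool[order(pool$ddg), , drop = FALSE]
  pool <- pool[!duplicated(paste(pool$chain, pool$pos)), , drop = FALSE]
  pool <- pool[order(pool$pos), , drop = FALSE]
  rownames(pool) <- NULL
  pairs <- build_pair_set(pool, structure, evaluator, radius)
  if (!is.null(prior_pairs) && nrow(prior_pairs)) {
    key <- function(df) paste(pmin(df$mut_a, df$mut_b),
                              pmax(df$mut_a, df$mut_b))
    hit <- match(key(pairs), key(prior_pairs))
    reuse <- !is.na(hit)
    pairs$ddg_pair[reuse] <- prior_pairs$ddg_pair[hit[reuse]]
    pairs$evaluated[reuse] <- prior_pairs$evaluated[hit[reuse]]
    pairs$additive[reuse] <- prior_pairs$additive[hit[reuse]]
  }
  g <- build_design_graph(pool, pairs)
  select_design(enumerate_maximal_cliques(g), pool, scenario)
}

#' Apply a design's substitutions to the query sequence
#'
#' @param query query sequence (string).
#' @param design a \code{stability_design}; mutations are applied at their
#'   query positions (\code{qpos} when present, else \code{pos}).
#' @return mutant sequence (string) of the same length.
#' @export
mutant_sequence <- function(query, design) {
  chars <- strsplit(query, "")[[1]]
  mt <- design$mutations
  if (nrow(mt) == 0L) return(query)
  pos <- if (!is.null(mt$qpos)) mt$qpos else mt$pos
  for (i in seq_len(nrow(mt))) {
    p <- pos[i]
    if (p < 1 || p > length(chars))
      stop("mutation position ", p, " outside the query sequence")
    if (chars[p] != mt$wt[i])
      stop("wild-type mismatch at position ", p, ": query has ", chars[p],
           ", design says ", mt$wt[i])
    chars[p] <- mt$mut[i]
  }
  paste(chars, collapse = "")
}
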