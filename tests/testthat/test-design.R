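singles_frame <- function(mutations, ddg, pos = NULL, chain = "A") {
  parsed <- lapply(mutations, parse_mutation)
  data.frame(
    mutation = mutations, chain = rep(chain, length(mutations)),
    pos = if (is.null(pos)) vapply(parsed, `[[`, 0L, "pos") else pos,
    qpos = if (is.null(pos)) vapply(parsed, `[[`, 0L, "pos") else pos,
    wt = vapply(parsed, `[[`, "", "wt"),
    mut = vapply(parsed, `[[`, "", "mut"),
    ddg = ddg, source = rep("saturation", length(mutations)),
    stringsAsFactors = FALSE)
}

graph_from_adj <- function(adj, ddg = rep(-1, nrow(adj))) {
  n <- nrow(adj)
  singles <- singles_frame(paste0("A", seq_len(n), "C"), ddg)
  pairs <- do.call(rbind, lapply(seq_len(n - 1), function(i) {
    do.call(rbind, lapply(seq(i + 1, n), function(j) {
      data.frame(mut_a = singles$mutation[i], mut_b = singles$mutation[j],
                 distance = 20, additive = TRUE, evaluated = TRUE,
                 # encode desired adjacency through the antagonism rule
                 ddg_pair = if (adj[i, j]) min(ddg[i], ddg[j]) - 1 else
                   min(ddg[i], ddg[j]) + 1,
                 stringsAsFactors = FALSE)
    }))
  }))
  build_design_graph(singles, pairs)
}

test_that("pair generation follows the radius rule and position exclusivity", {
  st <- synth_structure(40, seed = 7)
  qseq <- chain_sequence(st)$sequence
  ev <- surrogate_evaluator(st, seed = 7)
  mk <- function(p) {
    wt <- substr(qseq, p, p)
    paste0(wt, p, setdiff(stabiliforge:::AA_ALPHABET, wt)[1])
  }
  # positions 2,3 close; 2-30 and 3-30 distant on the helix
  singles <- singles_frame(c(mk(2), mk(3), mk(30)), c(-2, -2, -2))
  pairs <- build_pair_set(singles, st, ev)
  expect_equal(nrow(pairs), 3L)
  near <- pairs$distance <= 10
  expect_equal(sum(near), 1L)
  expect_false(any(pairs$additive[near]))
  expect_true(all(pairs$additive[!near]))
  expect_equal(pairs$ddg_pair[!near],
               rep(-4, 2))  # additive = sum of singles

  # same-position mutations never pair
  sp <- singles_frame(c("A2C", "A2D"), c(-1, -1))
  expect_equal(nrow(build_pair_set(sp, NULL, ev)), 0L)

  # n all-distant mutations give n(n-1)/2 additive pairs
  pos_far <- c(1, 10, 20, 30, 40)
  far <- singles_frame(vapply(pos_far, mk, ""), rep(-1, 5))
  pf <- build_pair_set(far, st, ev)
  expect_true(all(pf$distance > 10))
  expect_equal(nrow(pf), 10L)
  expect_true(all(pf$additive))
})

test_that("antagonistic edges are removed by the pair-energy rule", {
  singles <- singles_frame(c("A1C", "A2C"), c(-1, -2))
  mk_pair <- function(v) data.frame(mut_a = "A1C", mut_b = "A2C",
                                    distance = 5, ddg_pair = v,
                                    additive = FALSE, evaluated = TRUE)
  g_keep <- build_design_graph(singles, mk_pair(-2.5))
  expect_true(g_keep$adj["A1C", "A2C"])
  g_drop <- build_design_graph(singles, mk_pair(-1.8))
  expect_false(g_drop$adj["A1C", "A2C"])

  # additive landscape over stabilizing singles gives a complete graph
  k <- 6
  singles_k <- singles_frame(paste0("A", 1:k, "C"), -runif(k, 0.5, 3))
  pairs_k <- build_pair_set(singles_k, NULL,
                            synth_landscape(setNames(singles_k$ddg,
                                                     singles_k$mutation)))
  g <- build_design_graph(singles_k, pairs_k)
  expect_true(all(g$adj[upper.tri(g$adj)]))
})

test_that("maximal cliques of canonical small graphs", {
  tri <- matrix(TRUE, 3, 3); diag(tri) <- FALSE
  expect_equal(enumerate_maximal_cliques(tri), list(1:3))

  path <- matrix(FALSE, 3, 3)
  path[1, 2] <- path[2, 1] <- path[2, 3] <- path[3, 2] <- TRUE
  expect_equal(enumerate_maximal_cliques(path), list(c(1L, 2L), c(2L, 3L)))

  iso <- matrix(FALSE, 2, 2)
  expect_equal(enumerate_maximal_cliques(iso), list(1L, 2L))
  expect_equal(enumerate_maximal_cliques(matrix(FALSE, 0, 0)), list())
})

test_that("clique enumeration equals exhaustive subset enumeration", {
  for (seed in 1:100) {
    n <- sample(4:12, 1)
    adj <- random_adjacency(n, runif(1, 0.2, 0.7), seed = 1000 + seed)
    got <- enumerate_maximal_cliques(adj)
    want <- oracle_maximal_cliques(adj)
    expect_equal(got, want, label = paste("seed", seed))
  }
})

test_that("clique enumeration agrees with igraph as a second opinion", {
  skip_if_not_installed("igraph")
  adj <- random_adjacency(15, 0.45, seed = 99)
  got <- enumerate_maximal_cliques(adj)
  ig <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  want <- lapply(igraph::max_cliques(ig), function(v) sort(as.integer(v)))
  want <- want[order(vapply(want, function(cl)
    paste(sprintf("%06d", cl), collapse = " "), ""))]
  expect_equal(got, want)
})

test_that("design selection minimises total ddG with documented tie rules", {
  singles <- singles_frame(c("A1C", "A2C", "A3C"), c(-1.5, -1.5, -2.9))
  cliques <- list(c(1L, 2L), 3L)
  d <- select_design(cliques, singles)
  expect_equal(sort(d$mutations$mutation), c("A1C", "A2C"))
  expect_equal(d$total_score, -3.0)

  # equal sums: prefer the larger clique
  s2 <- singles_frame(paste0("A", 1:5, "C"), c(-3, -3, -2, -2, -2))
  d2 <- select_design(list(c(1L, 2L), c(3L, 4L, 5L)), s2)
  expect_equal(nrow(d2$mutations), 3L)

  # remaining ties: lexicographically smallest position list
  s3 <- singles_frame(paste0("A", 1:4, "C"), c(-1, -1, -1, -1))
  d3 <- select_design(list(c(2L, 4L), c(1L, 3L)), s3)
  expect_equal(d3$mutations$pos, c(1L, 3L))

  d_empty <- select_design(list(), s3)
  expect_equal(nrow(d_empty$mutations), 0L)
  expect_equal(d_empty$total_score, 0)
})

test_that("selected designs equal exhaustive search over landscapes", {
  for (seed in 1:50) {
    set.seed(2000 + seed)
    n <- sample(4:10, 1)
    pos <- sort(sample(1:40, n))
    muts <- paste0("A", pos, sample(setdiff(stabiliforge:::AA_ALPHABET, "A"),
                                    n, replace = TRUE))
    ddg <- -round(runif(n, 0.2, 3), 3)
    singles <- singles_frame(muts, ddg)
    # plant a few antagonistic overrides
    overrides <- NULL
    n_ant <- sample(0:3, 1)
    if (n_ant > 0) {
      sel <- replicate(n_ant, sort(sample(n, 2)), simplify = FALSE)
      overrides <- vapply(sel, function(ij)
        max(ddg[ij]) + runif(1, 0.1, 1), 0)
      names(overrides) <- vapply(sel, function(ij)
        paste(muts[ij[1]], muts[ij[2]], sep = "+"), "")
    }
    ev <- synth_landscape(setNames(ddg, muts), overrides)
    pairs <- build_pair_set(singles, NULL, ev)
    # force evaluation of every pair through the landscape (radius Inf)
    pairs$ddg_pair <- mapply(ev$pair, pairs$mut_a, pairs$mut_b)
    pairs$additive <- FALSE
    g <- build_design_graph(singles, pairs)
    d <- select_design(enumerate_maximal_cliques(g), singles)
    best <- oracle_best_design(singles, ev$pair)
    expect_equal(sort(d$mutations$mutation), sort(muts[best$idx]),
                 label = paste("seed", seed))
    expect_equal(d$total_score, best$score, tolerance = 1e-9)
  }
})

test_that("planting one antagonism removes that edge and splits the design", {
  muts <- paste0("A", c(3, 8, 15, 22), "C")
  ddg <- c(-1.2, -2.0, -1.6, -0.9)
  singles <- singles_frame(muts, ddg)
  ev_add <- synth_landscape(setNames(ddg, muts))
  pairs_add <- build_pair_set(singles, NULL, ev_add)
  g_add <- build_design_graph(singles, pairs_add)
  expect_true(all(g_add$adj[upper.tri(g_add$adj)]))
  d_add <- select_design(enumerate_maximal_cliques(g_add), singles)
  expect_setequal(d_add$mutations$mutation, muts)

  ev_ant <- synth_landscape(setNames(ddg, muts),
                            c("A8C+A15C" = -1.9))   # worse than -2.0
  pairs_ant <- build_pair_set(singles, NULL, ev_ant)
  pairs_ant$ddg_pair <- mapply(ev_ant$pair, pairs_ant$mut_a, pairs_ant$mut_b)
  pairs_ant$additive <- FALSE
  g_ant <- build_design_graph(singles, pairs_ant)
  removed <- !g_ant$adj["A8C", "A15C"]
  expect_true(removed)
  expect_equal(sum(g_add$adj) - sum(g_ant$adj), 2L)  # exactly one edge
  d_ant <- select_design(enumerate_maximal_cliques(g_ant), singles)
  expect_lt(sum(c("A8C", "A15C") %in% d_ant$mutations$mutation), 2L)
})

test_that("node deletion never improves the selected design", {
  set.seed(5)
  muts <- paste0("A", seq(2, 20, by = 2), "C")
  ddg <- -runif(10, 0.5, 2.5)
  ev <- synth_landscape(setNames(ddg, muts),
                        c("A2C+A4C" = max(ddg[1:2]) + 0.5))
  singles <- singles_frame(muts, ddg)
  pairs <- build_pair_set(singles, NULL, ev)
  pairs$ddg_pair <- mapply(ev$pair, pairs$mut_a, pairs$mut_b)
  pairs$additive <- FALSE
  full <- select_design(enumerate_maximal_cliques(
    build_design_graph(singles, pairs)), singles)
  for (drop in 1:10) {
    sub <- singles[-drop, , drop = FALSE]
    subpairs <- pairs[pairs$mut_a != muts[drop] & pairs$mut_b != muts[drop], ]
    d <- select_design(enumerate_maximal_cliques(
      build_design_graph(sub, subpairs)), sub)
    expect_gte(d$total_score, full$total_score - 1e-9)
  }
})

test_that("combined designs merge pools and resolve conflicts", {
  ev <- synth_landscape(c(A1C = -1, A10C = -2, A20C = -1.5, A30C = -1,
                          A40C = -0.8))
  d1 <- select_design(list(c(1L, 2L)),
                      singles_frame(c("A1C", "A10C"), c(-1, -2)), "energy-low")
  d2 <- select_design(list(c(1L, 2L, 3L)),
                      singles_frame(c("A20C", "A30C", "A40C"),
                                    c(-1.5, -1, -0.8)), "evolution")
  comb <- combined_design(d1, d2, NULL, ev, scenario = "combined-low")
  expect_equal(nrow(comb$mutations), 5L)
  expect_equal(comb$total_score, -6.3, tolerance = 1e-9)

  # same position in both pools: the more stabilizing single is kept
  d3 <- select_design(list(1L), singles_frame("A20C", -1.0), "energy-low")
  d4 <- select_design(list(1L), singles_frame("A20D", -2.0), "evolution")
  ev2 <- synth_landscape(c(A20C = -1.0, A20D = -2.0))
  comb2 <- combined_design(d3, d4, NULL, ev2)
  expect_equal(comb2$mutations$mutation, "A20D")

  # one empty pool: combined equals the other design's mutation set
  d_empty <- stability_design("evolution",
                              singles_frame(character(0), numeric(0)), 0)
  comb3 <- combined_design(d1, d_empty, NULL, ev)
  expect_setequal(comb3$mutations$mutation, d1$mutations$mutation)

  # engineered cross-pool antagonism: only one of the two appears
  ev3 <- synth_landscape(c(A1C = -1, A10C = -2, A20C = -1.5),
                         c("A10C+A20C" = -1.8))
  d5 <- select_design(list(c(1L, 2L)),
                      singles_frame(c("A1C", "A10C"), c(-1, -2)), "energy-low")
  d6 <- select_design(list(1L), singles_frame("A20C", -1.5), "evolution")
  comb4 <- combined_design(d5, d6, NULL, ev3)
  expect_lt(sum(c("A10C", "A20C") %in% comb4$mutations$mutation), 2L)
  # matches the exhaustive oracle on the 3-node union
  pool <- singles_frame(c("A1C", "A10C", "A20C"), c(-1, -2, -1.5))
  best <- oracle_best_design(pool, ev3$pair)
  expect_setequal(comb4$mutations$mutation, pool$mutation[best$idx])
})

test_that("mutant sequences apply substitutions with integrity checks", {
  d <- stability_design("energy-low",
                        singles_frame("D3N", -1), -1)
  expect_equal(mutant_sequence("ACDE", d), "ACNE")
  d0 <- stability_design("evolution",
                         singles_frame(character(0), numeric(0)), 0)
  expect_equal(mutant_sequence("ACDE", d0), "ACDE")
  bad <- stability_design("energy-low", singles_frame("Q4W", -1), -1)
  expect_error(mutant_sequence("ACDE", bad), "mismatch")
})
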