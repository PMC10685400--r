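test_that("saturation generates 19 substitutions per position", {
  expect_equal(nrow(saturation_candidates("ACD", positions = 2)), 19L)
  full <- saturation_candidates(strrep("A", 300))
  expect_equal(nrow(full), 5700L)
  expect_error(saturation_candidates("AXD", positions = 2), "standard")
  expect_error(saturation_candidates("ACD", positions = 4), "range")
  one <- saturation_candidates("ACD", positions = 2)
  expect_true(all(one$wt == "C"))
  expect_false("C" %in% one$mut)
})

test_that("back-to-consensus applies the majority and ratio rules", {
  # helper builds an MSA column with exact composition around wt 'A'
  col_msa <- function(comp) {
    # comp: named counts; query row contributes one 'A'
    col <- c("A", rep(names(comp), comp))
    msa(setNames(paste0(col, "C"),
                 c("query", paste0("s", seq_len(length(col) - 1)))), "query")
  }
  # S at 60%, wt A at 30%: majority candidate A -> S
  al <- col_msa(c(S = 12, A = 5, T = 2))   # with query: A=6/20, S=12/20
  out <- back_to_consensus(al)
  expect_equal(out$mutation, "A1S")
  expect_equal(out$source, "consensus-majority")
  expect_equal(out$consensus_freq, 0.6)

  # T at 42%, wt A at 8%: ratio rule (0.42 >= 0.40 and 0.42 >= 5 * 0.08)
  al2 <- col_msa(c(T = 21, A = 3, S = 7, G = 7, K = 6, M = 5))
  out2 <- back_to_consensus(al2)
  expect_equal(out2$mutation[1], "A1T")
  expect_equal(out2$source[1], "consensus-ratio")

  # T at 42% but wt A at 10%: 0.42 < 5 * 0.10 and < 0.50 -> no candidate
  al3 <- col_msa(c(T = 21, A = 4, S = 7, G = 7, K = 6, M = 5))
  out3 <- back_to_consensus(al3)
  expect_false("A1T" %in% out3$mutation)
})

test_that("consensus rules match a linear-scan oracle on random MSAs", {
  set.seed(21)
  for (rep_i in 1:8) {
    q <- paste(sample(stabiliforge:::AA_ALPHABET, 30, replace = TRUE),
               collapse = "")
    inj <- data.frame(pos = c(3, 9, 15),
                      aa = c("S", "T", "K"),
                      freq = c(0.52, 0.42, 0.38))
    # avoid planting the wild type itself
    qc <- strsplit(q, "")[[1]]
    inj <- inj[qc[inj$pos] != inj$aa, , drop = FALSE]
    al <- synth_msa(q, depth = 50, consensus_injections = inj,
                    seed = 100 + rep_i)
    got <- back_to_consensus(al)
    want <- oracle_consensus_calls(al)
    expect_equal(nrow(got), length(want))
    if (length(want)) {
      expect_equal(got$qpos, vapply(want, `[[`, 0L, "pos"))
      expect_equal(got$mut, vapply(want, `[[`, "", "mut"))
      expect_equal(got$source, vapply(want, `[[`, "", "src"))
    }
    # at most one candidate per position; rule guarantees on every call
    expect_false(anyDuplicated(got$qpos) > 0)
    maj <- got$source == "consensus-majority"
    expect_true(all(got$consensus_freq[maj] >= 0.5))
    expect_true(all(got$consensus_freq[!maj] >= 0.4 &
                      got$consensus_freq[!maj] >= 5 * got$wt_freq[!maj]))
  }
})

test_that("ancestral substitutions are read off the pairwise alignment", {
  expect_equal(ancestral_substitutions("ACDE", c(n1 = "ACNE"))$n1, "D3N")
  expect_equal(ancestral_substitutions("ACDE", c(n1 = "ACDE"))$n1,
               character(0))
  # deletion in the ancestor: only substitution columns are reported
  subs <- ancestral_substitutions("ACDEF", c(n1 = "ACEF"))$n1
  expect_true(all(grepl("^[A-Z][0-9]+[A-Z]$", subs)))
  for (s in subs) {
    m <- parse_mutation(s)
    expect_equal(substr("ACDEF", m$pos, m$pos), m$wt)
  }
  expect_warning(out <- ancestral_substitutions("ACDE", c(n1 = "", n2 = "ACNE")),
                 "empty")
  expect_equal(out$n2, "D3N")
})

test_that("recurrence filtering keeps mutations seen in multiple nodes", {
  nodes <- list(n1 = c("D3N", "E4Q"), n2 = c("D3N"), n3 = character(0),
                n4 = c("A1S"), n5 = c("A1S", "D3N"))
  out <- recurrent_ancestral_filter(nodes, min_nodes = 2)
  expect_setequal(out$mutation, c("A1S", "D3N"))
  expect_equal(out$n_nodes[out$mutation == "D3N"], 3L)
  out1 <- recurrent_ancestral_filter(nodes, min_nodes = 1)
  expect_setequal(out1$mutation, c("A1S", "D3N", "E4Q"))
  expect_true(all(out$source == "ancestral"))
})

test_that("position filters reject essential, conserved and correlated sites", {
  cand <- saturation_candidates("ACDEG")
  grades <- setNames(c(9L, 4L, 5L, 9L, 9L), 1:5)
  pol <- filter_policy("low")
  out <- apply_position_filters(cand, essential_positions = 1,
                                grades = grades,
                                correlated_positions = 4, policy = pol)
  reason_at <- function(p) unique(out$filter_reason[out$pos == p])
  expect_equal(reason_at(1), "essential")          # precedence over grade 9
  expect_equal(reason_at(2), "conserved")          # grade 4 rejected
  expect_equal(reason_at(3), "")                   # grade 5 passes
  expect_equal(reason_at(4), "correlated")
  expect_true(all(out$position_pass == (out$filter_reason == "")))
  expect_error(apply_position_filters(cand, 1, grades[1:3], 4, pol),
               "position")
})

test_that("mutation filters obey the risk policy", {
  al <- msa(c(query = "ACDEG", s1 = "SCDEG", s2 = "KCDEG"), "query")
  cand <- rbind(
    saturation_candidates("ACDEG", positions = 1),   # surface position
    saturation_candidates("ACDEG", positions = 3))   # buried position
  cand$filter_reason <- ""
  surface <- "A:1"
  low <- apply_mutation_filters(cand, al, surface, filter_policy("low"))
  high <- apply_mutation_filters(cand, al, surface, filter_policy("high"))

  a1k <- low$mutation == "A1K"      # neutral -> positive on the surface
  expect_equal(low$filter_reason[a1k], "charge-surface")
  expect_equal(high$filter_reason[high$mutation == "A1K"], "")
  # A1S present in the alignment column, no charge change: passes low-risk
  expect_equal(low$filter_reason[low$mutation == "A1S"], "")
  # A1W absent from column 1 of the alignment: msa-presence rejection
  expect_equal(low$filter_reason[low$mutation == "A1W"], "msa-presence")
  # buried charge change passes the charge-surface check
  d3k <- low$mutation == "D3K"
  expect_equal(low$filter_reason[d3k], "msa-presence")  # W/K absent in col 3
  d3e_low <- apply_mutation_filters(
    data.frame(mutation = "D3E", chain = "A", pos = 3L, qpos = 3L,
               wt = "D", mut = "E", source = "user", filter_reason = "",
               stringsAsFactors = FALSE),
    msa(c(query = "ACDEG", s1 = "ACEEG"), "query"), surface,
    filter_policy("low"))
  expect_equal(d3e_low$filter_reason, "")

  # msa-presence precedes charge-surface in the recorded reason
  a1r <- low$mutation == "A1R"   # absent from column AND charge-changing
  expect_equal(low$filter_reason[a1r], "msa-presence")
})

test_that("high-risk survivors are a superset of low-risk survivors", {
  set.seed(77)
  for (rep_i in 1:20) {
    n <- 20
    st <- synth_structure(n, seed = 200 + rep_i)
    qseq <- chain_sequence(st)$sequence
    al <- synth_msa(qseq, depth = 25, seed = 300 + rep_i)
    ann <- annotate_msa(al)
    sasa <- shrake_rupley_sasa(st, n_points = 240)
    surf <- surface_mask(sasa)
    cand <- saturation_candidates(qseq)
    grades <- setNames(as.integer(ann$grades), names(ann$grades))
    base <- apply_position_filters(cand, integer(0), grades,
                                   ann$correlated_positions,
                                   filter_policy("low"))
    low <- apply_mutation_filters(base, al, surf, filter_policy("low"))
    high <- apply_mutation_filters(base, al, surf, filter_policy("high"))
    low_ok <- low$mutation[low$filter_reason == ""]
    high_ok <- high$mutation[high$filter_reason == ""]
    expect_true(all(low_ok %in% high_ok))
  }
})
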