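make_state_changes <- function(changes, universe) {
  structure(list(changes = changes, universe = universe,
                 thresholds = de_thresholds(), n_conflicts = 0L,
                 n_unannotated = 0L),
            class = "state_change_set")
}

test_that("richness matches worked hypergeometric examples", {
  expect_equal(score_richness(20, 5, 8, 4), 896 / 15504)
  expect_equal(score_richness(100, 10, 20, 0), 1)
  expect_equal(score_richness(10, 10, 3, 3), 1)  # targets = universe
  expect_error(score_richness(10, 5, 3, 4), "inconsistent")
})

test_that("concordance matches worked binomial examples", {
  expect_equal(score_concordance(6, 6), 0.5^6)
  expect_equal(score_concordance(6, 3), 42 / 64)
  expect_equal(score_concordance(8, 0), 1)
  expect_equal(score_concordance(0, 0), 1)
  expect_error(score_concordance(6, 3, q = 1.5), "q must")
  expect_error(score_concordance(6, 7), "n_correct")
})

test_that("richness equals exhaustive enumeration for universes up to 12", {
  for (N in c(5, 8, 12)) {
    for (targets in c(1, 3, N %/% 2, N)) {
      for (changed in c(0, 1, N %/% 3, N %/% 2)) {
        for (overlap in 0:min(targets, changed)) {
          expect_equal(
            score_richness(N, targets, changed, overlap),
            richness_brute(N, targets, changed, overlap),
            tolerance = 1e-12,
            label = sprintf("N=%d t=%d c=%d k=%d", N, targets, changed,
                            overlap))
        }
      }
    }
  }
})

test_that("concordance equals enumeration over all direction assignments", {
  for (n in c(1, 4, 7, 12)) {
    for (c in 0:n) {
      expect_equal(score_concordance(n, c), concordance_brute(n, c),
                   tolerance = 1e-12, label = sprintf("n=%d c=%d", n, c))
    }
  }
})

test_that("p-values are monotone in the observed counts", {
  rich <- score_richness(50, 10, 15, 0:10)
  expect_true(all(diff(rich) <= 1e-12))
  conc <- score_concordance(10, 0:10)
  expect_true(all(diff(conc) <= 1e-12))
})

test_that("binomial tails are complementary", {
  for (n in c(3, 6, 11)) {
    for (c in 1:n) {
      expect_equal(score_concordance(n, c) + pbinom(c - 1, n, 0.5), 1,
                   tolerance = 1e-12)
    }
  }
})

test_that("candidacy requires the minimum of measured downstream targets", {
  g <- random_graph(2, n_ctrl = 6, n_genes = 15)
  universe <- sprintf("g%02d", 1:15)
  cfg <- rcr_config(min_targets = 4)
  cand <- candidate_hypotheses(g, universe, cfg)
  n_targets <- vapply(unique(g$causal_edges$source), function(nd)
    nrow(downstream_mrna_targets(g, nd)), 1L)
  eligible <- sort(names(n_targets)[n_targets >= 4])
  expect_setequal(unique(cand$node_id), eligible)
  expect_equal(nrow(cand), 2 * length(eligible))  # both directions

  # universe filter: measured targets only
  small_universe <- sprintf("g%02d", 1:3)
  cand2 <- candidate_hypotheses(g, small_universe, cfg)
  expect_equal(nrow(cand2), 0)

  # mRNA nodes are never candidates
  expect_false(any(grepl("^exp\\(", cand$node_id)))
})

test_that("hypothesis counts and significance follow the scoring contract", {
  g <- toy_graph()
  # kaof(CDK2): m1 ambiguous via taof(TF1)? No: ambiguity is per-path from
  # the scored node; kaof(CDK2) reaches m1 +, m2 +, m3 -
  sc <- make_state_changes(c(m1 = 1L, m2 = 1L, m3 = -1L),
                           c("m1", "m2", "m3", "m4", "m5"))
  cfg <- rcr_config(min_targets = 3, min_consistent = 3,
                    alpha_concordance = 0.15)
  hyp <- generate_hypotheses(g, sc, cfg)
  up <- hyp[hyp$node_id == "kaof(CDK2)" & hyp$direction == 1, ]
  expect_equal(up$n_targets, 3)
  expect_equal(up$n_overlap, 3)
  expect_equal(up$n_correct, 3)
  expect_equal(up$n_contra, 0)
  expect_equal(up$richness_p, score_richness(5, 3, 3, 3))
  expect_equal(up$concordance_p, 0.5^3)
  expect_true(up$significant)
  down <- hyp[hyp$node_id == "kaof(CDK2)" & hyp$direction == -1, ]
  expect_equal(down$n_correct, 0)
  expect_equal(down$richness_p, up$richness_p)
  expect_false(down$significant)
  expect_equal(up$n_correct + up$n_contra + up$n_ambiguous, up$n_overlap)
})

test_that("ambiguous-sign targets count for richness, not concordance", {
  nodes <- data.frame(
    node_id = c("a", paste0("exp(m", 1:5, ")")),
    label = c("a", paste0("exp(m", 1:5, ")")),
    entity_class = c("activity", rep("mRNA", 5)),
    base_entity = c("A", paste0("m", 1:5)), modification = "",
    activity_kind = c("kinase", rep("", 5)), species_scope = "",
    block_tag = "", stringsAsFactors = FALSE)
  edges <- data.frame(
    source = "a",
    target = c("exp(m1)", "exp(m1)", "exp(m2)", "exp(m3)", "exp(m4)",
               "exp(m5)"),
    sign = c(1L, -1L, 1L, 1L, 1L, 1L), stringsAsFactors = FALSE)
  g <- causal_graph(nodes, edges)
  sc <- make_state_changes(c(m1 = 1L, m2 = 1L, m3 = 1L),
                           c(paste0("m", 1:5), "x1", "x2"))
  hyp <- generate_hypotheses(g, sc, rcr_config(min_targets = 4,
                                               min_consistent = 2))
  up <- hyp[hyp$node_id == "a" & hyp$direction == 1, ]
  expect_equal(up$n_overlap, 3)      # m1 (ambiguous), m2, m3
  expect_equal(up$n_ambiguous, 1)
  expect_equal(up$n_correct, 2)      # m2, m3 only
  expect_equal(up$richness_p, score_richness(7, 5, 3, 3))
  expect_equal(up$concordance_p, score_concordance(2, 2))
})

test_that("empty state-change set gives richness 1 and no significance", {
  g <- random_graph(6, n_ctrl = 4, n_genes = 12)
  sc <- make_state_changes(setNames(integer(0), character(0)),
                           sprintf("g%02d", 1:12))
  hyp <- generate_hypotheses(g, sc, rcr_config(min_targets = 2))
  expect_true(all(hyp$richness_p == 1))
  expect_false(any(hyp$significant))
})

test_that("negating all state changes swaps directional concordance", {
  g <- random_graph(8, n_ctrl = 5, n_genes = 12)
  genes <- sprintf("g%02d", 1:12)
  set.seed(31)
  changed <- sample(genes, 6)
  sc <- make_state_changes(setNames(sample(c(-1L, 1L), 6, TRUE), changed),
                           genes)
  flipped <- sc
  flipped$changes <- -sc$changes
  cfg <- rcr_config(min_targets = 2)
  h1 <- generate_hypotheses(g, sc, cfg)
  h2 <- generate_hypotheses(g, flipped, cfg)
  key <- function(h) h[order(h$node_id, h$direction), ]
  a <- key(h1); b <- key(h2)
  b_swapped <- b
  b_swapped$direction <- -b_swapped$direction
  b_swapped <- key(b_swapped)
  expect_equal(a$concordance_p, b_swapped$concordance_p)
  expect_equal(a$n_correct, b_swapped$n_correct)
  expect_equal(a$richness_p, b$richness_p)
})

test_that("output ordering is deterministic", {
  g <- random_graph(9, n_ctrl = 5, n_genes = 12)
  genes <- sprintf("g%02d", 1:12)
  sc <- make_state_changes(setNames(rep(1L, 4), genes[1:4]), genes)
  cfg <- rcr_config(min_targets = 2)
  h1 <- generate_hypotheses(g, sc, cfg)
  h2 <- generate_hypotheses(g, sc, cfg)
  expect_identical(h1, h2)
  expect_false(is.unsorted(h1$concordance_p))
})
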