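test_that("quantile normalization matches the mean-of-sorted-columns oracle", {
  m <- cbind(a = c(1, 2, 3), b = c(4, 5, 6))
  qn <- quantile_normalize(m)
  expect_equal(unname(qn[, 1]), c(2.5, 3.5, 4.5))
  expect_equal(unname(qn[, 2]), c(2.5, 3.5, 4.5))

  # order scrambled in one column: values follow ranks
  m2 <- cbind(a = c(3, 1, 2), b = c(4, 5, 6))
  qn2 <- quantile_normalize(m2)
  expect_equal(unname(qn2[, 1]), c(4.5, 2.5, 3.5))

  # identical columns are a fixed point
  m3 <- cbind(x = c(5, 1, 9), y = c(5, 1, 9))
  expect_equal(quantile_normalize(m3), m3)

  # single row: every entry becomes the row mean
  m4 <- matrix(c(2, 8, 5), nrow = 1)
  expect_equal(unname(quantile_normalize(m4)[1, ]), rep(5, 3))
})

test_that("quantile normalization equalizes column sums and is idempotent", {
  set.seed(11)
  m <- matrix(rexp(200, 1 / 100), ncol = 4)
  qn <- quantile_normalize(m)
  expect_equal(max(colSums(qn)) - min(colSums(qn)), 0)
  expect_equal(quantile_normalize(qn), qn)
  for (j in 2:4) expect_equal(sort(qn[, j]), sort(qn[, 1]))
  expect_error(quantile_normalize(matrix(c(1, NA, 2, 3), 2)), "missing")
})

test_that("quantile normalization agrees with limma on tie-free data", {
  set.seed(12)
  m <- matrix(runif(300), ncol = 3)
  expect_equal(unname(quantile_normalize(m)),
               unname(limma::normalizeQuantiles(m)))
})

test_that("median-polish summarization recovers additive structure", {
  # 2 probes x 2 samples with additive row/column structure (log2 scale):
  # row effects (0, 2), column effects (1, 3) around overall 5
  lg <- matrix(c(5 + 0 + 1, 5 + 0 + 3,
                 5 + 2 + 1, 5 + 2 + 3), nrow = 2, byrow = TRUE,
               dimnames = list(c("p1", "p2"), c("s1", "s2")))
  out <- rma_summarize(2^lg, c("ps1", "ps1"), background = FALSE,
                       normalize = FALSE)
  # overall + column effects: medpolish centers rows at their median
  expect_equal(unname(out["ps1", ]), c(6 + 1, 6 + 3))

  # probes identical across samples: summary equals the common log2 value
  same <- matrix(2^c(7, 7, 7, 7), nrow = 2,
                 dimnames = list(c("p1", "p2"), c("s1", "s2")))
  out2 <- rma_summarize(same, c("ps", "ps"), background = FALSE,
                        normalize = FALSE)
  expect_equal(unname(out2["ps", ]), c(7, 7))

  # single-probe probe sets: identity on the (non-normalized) log2 values
  m <- matrix(2^c(3, 4, 5, 6), nrow = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  out3 <- rma_summarize(m, c("psA", "psB"), background = FALSE,
                        normalize = FALSE)
  expect_equal(unname(out3["psA", ]), c(3, 5))
  expect_equal(unname(out3["psB", ]), c(4, 6))
})

test_that("full RMA-style chain returns finite log2 summaries per probe set", {
  set.seed(5)
  m <- matrix(rexp(600, 1 / 200) + 20, ncol = 6,
              dimnames = list(sprintf("p%03d", 1:100), sprintf("s%d", 1:6)))
  sets <- rep(sprintf("ps%02d", 1:20), each = 5)
  out <- rma_summarize(m, sets)
  expect_equal(dim(out), c(20, 6))
  expect_true(all(is.finite(out)))
  expect_error(rma_summarize(m, sets[-1]), "length")
})

test_that("two-group fit matches the textbook pooled t", {
  lg <- rbind(gA = c(1.0, 1.2, 0.8, 2.0, 2.3, 1.7),
              gB = c(5.0, 5.1, 4.9, 5.0, 5.2, 4.8))
  groups <- rep(c("control", "treated"), each = 3)
  res <- fit_two_group(lg, groups, moderation = "none")
  for (g in rownames(lg)) {
    tt <- t.test(lg[g, 4:6], lg[g, 1:3], var.equal = TRUE)
    row <- res[res$probe_id == g, ]
    expect_equal(row$t_statistic, unname(tt$statistic), tolerance = 1e-12)
    expect_equal(row$raw_p, tt$p.value, tolerance = 1e-12)
    expect_equal(row$log2_fc, unname(diff(rev(tt$estimate))), tolerance = 1e-12)
  }
})

test_that("degenerate and null contrasts are handled", {
  lg <- rbind(flat = c(2, 2, 2, 2, 2, 2),
              sep = c(0, 0, 0, 1, 1, 1))
  groups <- rep(c("control", "treated"), each = 3)
  # the degenerate probe propagates an NA p-value through BH, with a warning
  expect_warning(res <- fit_two_group(lg, groups, moderation = "none"),
                 "missing")
  expect_equal(res$log2_fc[1], 0)
  expect_equal(res$t_statistic[1], 0)
  expect_equal(res$raw_p[1], 1)
  expect_true(res$degenerate[2])
  expect_true(is.infinite(res$t_statistic[2]))
  expect_true(is.na(res$raw_p[2]))
  expect_error(fit_two_group(lg, c("control", rep("treated", 5))), "2 samples")
})

test_that("empirical-Bayes moderation matches the limma moderated t", {
  set.seed(21)
  lg <- matrix(rnorm(300, 8, 1), ncol = 6,
               dimnames = list(sprintf("p%02d", 1:50), NULL))
  lg[1:5, 4:6] <- lg[1:5, 4:6] + 2
  groups <- rep(c("control", "treated"), each = 3)
  res <- fit_two_group(lg, groups, moderation = "empirical-bayes")
  design <- cbind(1, groups == "treated")
  fit <- limma::eBayes(limma::lmFit(lg, design))
  expect_equal(res$t_statistic, unname(fit$t[, 2]), tolerance = 1e-8)
  expect_equal(res$raw_p, unname(fit$p.value[, 2]), tolerance = 1e-8)
})

test_that("BH adjustment equals its brute-force step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_warning(out <- bh_adjust(c(0.1, NA, 0.5)), "missing")
  expect_true(is.na(out[2]))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")

  set.seed(7)
  for (i in 1:50) {
    p <- runif(sample(1:50, 1))
    expect_equal(bh_adjust(p), bh_brute(p))
  }
})

test_that("state-change gates apply p, fold-change and abundance filters", {
  res <- data.frame(
    probe_id = c("p1", "p2", "p3", "p4", "p5"),
    log2_fc = c(log2(1.4), log2(1.2), -log2(1.5), log2(1.5), log2(2)),
    t_statistic = 1, raw_p = 0.01,
    adj_p = c(0.04, 0.04, 0.04, 0.2, 0.04),
    mean_intensity_control = c(300, 300, 300, 300, 100),
    mean_intensity_treated = c(300, 300, 100, 300, 200),
    degenerate = FALSE, stringsAsFactors = FALSE)
  p2g <- setNames(paste0("G", 1:5), paste0("p", 1:5))

  sc <- call_state_changes(res, de_thresholds(), p2g)
  expect_equal(sc$changes, c(G1 = 1L, G3 = -1L, G5 = 1L))
  expect_setequal(sc$universe, paste0("G", 1:5))

  # abundance floor at 250: p3 passes via control mean, p5 drops
  sc2 <- call_state_changes(res, de_thresholds(abundance_min = 250), p2g)
  expect_equal(sc2$changes, c(G1 = 1L, G3 = -1L))

  # unannotated probes drop out of the universe and are counted
  p2g_miss <- p2g[-5]
  sc3 <- call_state_changes(res, de_thresholds(), p2g_miss)
  expect_false("G5" %in% sc3$universe)
  expect_equal(sc3$n_unannotated, 1L)
})

test_that("opposite-direction passing probes of one gene drop with a conflict count", {
  res <- data.frame(
    probe_id = c("p1", "p2"),
    log2_fc = c(1, -1), t_statistic = 1, raw_p = 0.01, adj_p = 0.01,
    mean_intensity_control = 500, mean_intensity_treated = 500,
    degenerate = FALSE, stringsAsFactors = FALSE)
  sc <- call_state_changes(res, de_thresholds(),
                           c(p1 = "G1", p2 = "G1"))
  expect_equal(length(sc$changes), 0)
  expect_equal(sc$n_conflicts, 1L)
  expect_equal(sc$universe, "G1")
})

test_that("state-change count is non-increasing as thresholds tighten", {
  mat <- toy_expression(
    setNames(rep(8, 40), sprintf("g%02d", 1:40)),
    setNames(c(rep(9.2, 10), rep(8, 30)), sprintf("g%02d", 1:40)),
    noise_sd = 0.3, seed = 9)
  chain <- function(th) length(state_change_chain(mat, th)$state_changes$changes)
  base <- chain(de_thresholds())
  expect_lte(chain(de_thresholds(adj_p_max = 0.01)), base)
  expect_lte(chain(de_thresholds(fold_change_min = 2)), base)
  expect_lte(chain(de_thresholds(abundance_min = 400)), base)
})
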