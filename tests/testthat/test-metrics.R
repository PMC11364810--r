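test_that("accuracy and kappa follow their definitions", {
  expect_equal(accuracy(diag(c(10, 10, 10, 10))), 1.0)
  expect_equal(accuracy(rbind(c(8, 2), c(3, 7))), 15 / 20)
  expect_equal(accuracy(rbind(c(0, 5), c(5, 0))), 0.0)
  expect_error(accuracy(matrix(0, 2, 2)), "empty")

  expect_equal(kappa(1, 4), 1)
  expect_equal(kappa(0.25, 4), 0)
  expect_equal(kappa(0.5, 2), 0)
  expect_error(kappa(0.5, 1), "classes")
  # strictly increasing in observed accuracy
  p <- seq(0, 1, by = 0.05)
  expect_true(all(diff(kappa(p, 4)) > 0))
})

test_that("confusion-matrix metrics agree with direct label comparison", {
  set.seed(14)
  for (i in 1:5) {
    n_cls <- sample(2:5, 1)
    truth <- sample(0:(n_cls - 1L), 60, replace = TRUE)
    pred <- ifelse(stats::runif(60) < 0.6, truth,
                   sample(0:(n_cls - 1L), 60, replace = TRUE))
    cm <- confusion_matrix(truth, pred, n_cls)
    expect_identical(sum(cm), 60L)
    expect_equal(accuracy(cm), mean(truth == pred))
    expect_equal(kappa_from_cm(cm, "balanced"),
                 (mean(truth == pred) - 1 / n_cls) / (1 - 1 / n_cls))
    # marginal-chance variant equals the classical hand formula
    pe <- sum(table(factor(truth, levels = 0:(n_cls - 1))) *
                table(factor(pred, levels = 0:(n_cls - 1)))) / 60^2
    expect_equal(kappa_from_cm(cm, "marginal"),
                 (mean(truth == pred) - pe) / (1 - pe))
  }
})

test_that("aggregation reproduces the published subject-specific summary", {
  row <- bci_reference_row("ctnet", "iv2a", "subject_specific")
  agg <- aggregate_results(row, kappas = kappa(row / 100, 4))
  expect_equal(round(agg$mean_accuracy, 2), 82.52)
  expect_equal(round(agg$sd_accuracy, 2), 9.61)
  expect_equal(round(agg$mean_kappa, 4), 0.7670)
  # order-invariance and the two-equal-subjects degenerate case
  agg_rev <- aggregate_results(rev(row))
  expect_equal(agg_rev$mean_accuracy, agg$mean_accuracy)
  expect_equal(agg_rev$sd_accuracy, agg$sd_accuracy)
  expect_equal(aggregate_results(c(70, 70))$sd_accuracy, 0)
  expect_error(aggregate_results(75), ">= 2")
})

test_that("Hedges' g matches hand-worked values and is antisymmetric", {
  r <- hedges_g(c(1, 2, 3), c(2, 3, 4))
  expect_equal(r$d, -1)
  expect_equal(r$g, -0.8)          # correction 1 - 3/15
  expect_equal(hedges_g(c(2, 3, 4), c(1, 2, 3))$g, 0.8)
  set.seed(3)
  x <- rnorm(9, 80, 5); y <- rnorm(9, 76, 6)
  expect_equal(hedges_g(x, y)$g, -hedges_g(y, x)$g, tolerance = 1e-12)
  expect_lte(abs(hedges_g(x, y)$g), abs(hedges_g(x, y)$d))
  expect_error(hedges_g(c(1, 1), c(1, 1)), "zero pooled")
  expect_error(hedges_g(1, c(1, 2)), ">= 2")
})

test_that("exact Wilcoxon reproduces the published p-values", {
  ct <- bci_reference_row("ctnet", "iv2a", "subject_specific")
  sh <- bci_reference_row("shallowconvnet", "iv2a", "subject_specific")
  ee <- bci_reference_row("eegnet", "iv2a", "subject_specific")
  # all 9 differences positive: p = 1/512
  expect_true(all(ct - sh > 0))
  expect_equal(wilcoxon_exact_p(ct, sh, "greater"), 1 / 512)
  expect_equal(round(wilcoxon_exact_p(ct, sh, "greater"), 4), 0.0020)
  # one negative difference tied in magnitude: midranks give p = 3/512
  expect_equal(wilcoxon_exact_p(ct, ee, "greater"), 3 / 512)
  expect_equal(round(wilcoxon_exact_p(ct, ee, "greater"), 4), 0.0059)
})

test_that("exact Wilcoxon equals brute-force sign enumeration for n <= 10", {
  # constant positive shift, n = 5: only the all-positive assignment is as
  # extreme, p = 1/32
  x <- c(5, 9, 2, 7, 4)
  expect_equal(wilcoxon_exact_p(x + 1, x, "greater"), 1 / 32)
  set.seed(8)
  for (i in 1:20) {
    n <- sample(3:10, 1)
    x <- round(stats::rnorm(n, 1, 2), 1)   # rounding provokes ties and zeros
    y <- round(stats::rnorm(n, 0, 2), 1)
    if (all(x == y)) next
    for (alt in c("greater", "less", "two_sided")) {
      expect_equal(wilcoxon_exact_p(x, y, alt), brute_wilcoxon(x, y, alt),
                   tolerance = 1e-12)
    }
    # cross-check against the stock exact test when it applies (no ties/zeros)
    d <- x - y
    if (all(d != 0) && !any(duplicated(abs(d)))) {
      ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE,
                                alternative = "greater")$p.value
      expect_equal(wilcoxon_exact_p(x, y, "greater"), ref, tolerance = 1e-12)
    }
  }
  expect_error(wilcoxon_exact_p(c(1, 2), c(1, 2)), "zero")
  # exact-distribution boundary: both one-sided p-values overlap at w_obs
  xx <- c(3, 1, 4, 1, 5); yy <- c(2, 2, 3, 2, 4)
  expect_gte(wilcoxon_exact_p(xx, yy, "greater") +
               wilcoxon_exact_p(xx, yy, "less"), 1)
})

test_that("LOSO reference rows reproduce the published means", {
  l2a <- aggregate_results(bci_reference_row("ctnet", "iv2a", "loso"))
  l2b <- aggregate_results(bci_reference_row("ctnet", "iv2b", "loso"))
  expect_equal(round(l2a$mean_accuracy, 2), 58.64)
  expect_equal(round(l2b$mean_accuracy, 2), 76.27)
})
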