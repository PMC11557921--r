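# ROC/AUC, cutoff, 2x2 metrics, odds ratios, regressions, median CI.

test_that("AUC matches hand-worked examples and the pair-counting oracle", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))$auc, 1.0)
  expect_equal(roc_auc(c(1, 3, 2, 4), c(0, 0, 1, 1))$auc, 0.75)
  expect_equal(roc_auc(rep(2, 6), c(0, 1, 0, 1, 0, 1))$auc, 0.5)
  set.seed(21)
  for (i in 1:300) {
    n <- sample(4:50, 1)
    scores <- sample(1:8, n, replace = TRUE)     # heavy ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels)$auc,
                 auc_bruteforce(scores, labels))
  }
})

test_that("AUC symmetry and single-class error", {
  set.seed(22)
  scores <- rnorm(40)
  labels <- c(0, 1, sample(0:1, 38, replace = TRUE))
  expect_equal(roc_auc(-scores, labels)$auc, 1 - roc_auc(scores, labels)$auc)
  expect_error(roc_auc(scores, rep(1, 40)), "both endpoint classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(23)
  for (i in 1:20) {
    scores <- sample(1:10, 60, replace = TRUE)
    labels <- c(0, 1, sample(0:1, 58, replace = TRUE))
    ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                          direction = "<", levels = c(0, 1))))
    expect_equal(roc_auc(scores, labels)$auc, ref)
  }
})

test_that("Youden cutoff maximizes J with ties broken toward lower thresholds", {
  expect_equal(youden_cutoff(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1))), 2)
  # flat ROC: every J equal -> lowest threshold
  expect_equal(youden_cutoff(roc_auc(c(3, 3, 3, 3), c(0, 1, 0, 1))), 3)
  # enumerated check against brute force over all candidate thresholds
  set.seed(24)
  for (i in 1:100) {
    scores <- sample(1:6, 30, replace = TRUE)
    labels <- c(0, 1, sample(0:1, 28, replace = TRUE))
    roc <- roc_auc(scores, labels)
    j_at <- function(ct) {
      mean(scores[labels == 1] > ct) + mean(scores[labels == 0] <= ct) - 1
    }
    js <- vapply(roc$thresholds, j_at, numeric(1))
    best <- roc$thresholds[js >= max(js) - 1e-12]
    expect_equal(youden_cutoff(roc), min(best))
  }
})

test_that("2x2 tables use the strict > rule and conserve counts", {
  t <- two_by_two(c(8, 7), c(1, 0), 7)
  expect_equal(c(t$tp, t$fp, t$fn, t$tn), c(1, 0, 0, 1))
  t <- two_by_two(c(1, 2), c(1, 0), 5)
  expect_equal(c(t$tp, t$fp), c(0, 0))
  set.seed(25)
  scores <- rnorm(20); labels <- c(0, 1, sample(0:1, 18, replace = TRUE))
  for (ct in c(-1, 0, 0.5)) {
    t <- two_by_two(scores, labels, ct)
    expect_equal(t$tp + t$fp + t$fn + t$tn, 20)
    expect_equal(t$tp, sum(scores > ct & labels == 1))
    # metrics invariant under strictly monotone transform of scores+cutoff
    t2 <- two_by_two(exp(scores), labels, exp(ct))
    expect_equal(diagnostic_metrics(t), diagnostic_metrics(t2))
  }
})

test_that("diagnostic metrics match direct ratios and flag undefined cells", {
  m <- diagnostic_metrics(list(tp = 90, fp = 60, fn = 34, tn = 140))
  expect_equal(m$sensitivity, 90 / 124, tolerance = 1e-12)
  expect_equal(m$specificity, 0.7)
  expect_equal(m$ppv, 0.6)
  expect_equal(m$npv, 140 / 174, tolerance = 1e-12)
  m <- diagnostic_metrics(list(tp = 1, fp = 0, fn = 0, tn = 1))
  expect_equal(unlist(m[1:4]), c(sensitivity = 1, specificity = 1,
                                 ppv = 1, npv = 1))
  m <- diagnostic_metrics(list(tp = 0, fp = 0, fn = 2, tn = 3))
  expect_true(is.na(m$ppv))
  expect_true("ppv" %in% m$undefined)
})

test_that("odds ratio: cross-product, invariances, Haldane flag, degenerate tables", {
  expect_equal(odds_ratio(list(tp = 1, fp = 1, fn = 1, tn = 1))$or, 1)
  expect_equal(odds_ratio(list(tp = 2, fp = 1, fn = 1, tn = 2))$or, 4)
  expect_equal(odds_ratio(list(tp = 90, fp = 60, fn = 34, tn = 140))$or,
               90 * 140 / (60 * 34), tolerance = 1e-12)
  # swapping both rows and both columns leaves OR unchanged; one swap inverts
  o1 <- odds_ratio(list(tp = 12, fp = 5, fn = 7, tn = 20))
  o2 <- odds_ratio(list(tp = 20, fp = 7, fn = 5, tn = 12))
  o3 <- odds_ratio(list(tp = 5, fp = 12, fn = 20, tn = 7))
  expect_equal(o1$or, o2$or)
  expect_equal(o1$or, 1 / o3$or, tolerance = 1e-12)
  # zero cell: Haldane-Anscombe correction applied and flagged
  oz <- odds_ratio(list(tp = 5, fp = 0, fn = 3, tn = 10))
  expect_true(oz$haldane_corrected)
  expect_equal(oz$or, (5.5 * 10.5) / (0.5 * 3.5), tolerance = 1e-12)
  # empty margin: undefined, not a number
  od <- odds_ratio(list(tp = 0, fp = 0, fn = 3, tn = 10))
  expect_true(od$undefined)
  expect_true(is.na(od$or))
})

test_that("logistic fit recovers known effects and the closed-form intercept", {
  set.seed(26)
  # null case: slope near 0
  x <- rnorm(4000); y <- rbinom(4000, 1, 0.5)
  f <- logistic_fit(x, y)
  expect_lt(abs(f$estimate), 0.12)
  expect_gt(f$p_value, 0.001)
  # slope recovery
  x <- rnorm(5000); y <- rbinom(5000, 1, plogis(x))
  f <- logistic_fit(x, y, name = "score")
  expect_lt(abs(f$estimate - 1), 0.1)
  # intercept-only closed form
  y <- rep(c(1, 0), c(30, 70))
  f0 <- logistic_fit(NULL, y)
  expect_equal(f0$estimate, log(0.3 / 0.7), tolerance = 1e-6)
})

test_that("logistic fit rejects single-class endpoints and perfect separation", {
  expect_error(logistic_fit(rnorm(10), rep(1, 10)), "single class")
  x <- c(1, 2, 3, 10, 11, 12); y <- c(0, 0, 0, 1, 1, 1)
  expect_error(logistic_fit(x, y, name = "lods"), "separation.*lods")
})

test_that("OLS table reproduces exact fits and flags rank deficiency", {
  set.seed(27)
  d <- data.frame(a = rnorm(50), b = rnorm(50))
  d$y <- 2 + 3 * d$a - 1 * d$b  # no noise: exact recovery ("perfect fit"
                                # warnings from the summary are expected)
  tab <- suppressWarnings(ols_multivariate(d, "y", c("a", "b")))
  expect_equal(tab$estimate, c(2, 3, -1), tolerance = 1e-10)
  # permuting covariates permutes rows only
  tab2 <- suppressWarnings(ols_multivariate(d, "y", c("b", "a")))
  expect_equal(sort(tab$term), sort(tab2$term))
  expect_equal(tab$estimate[tab$term == "a"], tab2$estimate[tab2$term == "a"])
  # CI = estimate +/- t_crit * SE
  d$y <- d$y + rnorm(50)
  tab <- ols_multivariate(d, "y", c("a", "b"))
  tcrit <- qt(0.975, df = 50 - 3)
  expect_equal(tab$ci_high - tab$estimate, tcrit * tab$se, tolerance = 1e-10)
  # collinear column named in the error
  d$c <- d$a + d$b
  expect_error(ols_multivariate(d, "y", c("a", "b", "c")), "c")
})

test_that("median CI comes from order statistics and behaves at edges", {
  expect_equal(median_with_ci(c(1, 2, 3))$median, 2)
  m <- median_with_ci(rep(7, 20))
  expect_equal(c(m$ci_low, m$ci_high), c(7, 7))
  set.seed(28)
  x <- rnorm(101)
  m <- median_with_ci(x)
  s <- sort(x)
  expect_true(m$ci_low %in% s && m$ci_high %in% s)
  expect_lte(m$ci_low, m$median); expect_gte(m$ci_high, m$median)
  # coverage of the selected order-statistic pair is >= 95%
  l <- which(s == m$ci_low)[1]; u <- which(s == m$ci_high)[1]
  expect_gte(pbinom(u - 1, 101, 0.5) - pbinom(l - 1, 101, 0.5), 0.95)
})

test_that("mRS dichotomization follows the favorable rule", {
  expect_equal(dichotomize_outcome(c(0, 2, 3, 6)),
               c(TRUE, TRUE, FALSE, FALSE))
  expect_error(dichotomize_outcome(7), "mrs")
})
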