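test_that("AUC equals brute-force pair counting on random small instances", {
  expect_equal(auc(c(0.9, 0.4, 0.5, 0.3), c(1, 1, 0, 0))$auc, 0.75)
  set.seed(51)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # plenty of ties
    expect_equal(auc(s, y)$auc, auc_bruteforce(s, y), tolerance = 1e-12)
  }
  expect_equal(auc(c(3, 4, 1, 2), c(1, 1, 0, 0))$auc, 1)
  expect_equal(auc(rep(2, 6), c(1, 1, 1, 0, 0, 0))$auc, 0.5)
  expect_error(auc(1:4, rep(1, 4)), "both classes")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(52)
  s <- rnorm(50); y <- rbinom(50, 1, 0.5); y[1:2] <- 0:1
  expect_equal(auc(s, y)$auc, auc(exp(s), y)$auc)
  expect_equal(auc(s, y)$auc, auc(qlogis(plogis(s)), y)$auc, tolerance = 1e-12)
})

test_that("DeLong variance behaves as structural-component theory predicts", {
  set.seed(53)
  s <- rnorm(40); y <- rep(0:1, 20)
  v1 <- delong_ci(s, y)$var
  # duplicating every observation roughly halves the variance
  v2 <- delong_ci(rep(s, 2), rep(y, 2))$var
  expect_equal(v2 / v1, 0.5, tolerance = 0.06)
  # separated data: zero-width interval with a warning
  expect_warning(ci <- delong_ci(c(1, 2, 3, 10, 11, 12), rep(0:1, each = 3)),
                 "degenerate")
  expect_identical(ci$ci, c(1, 1))
})

test_that("DeLong CI covers the true AUC at the nominal rate", {
  set.seed(54)
  mu <- 1       # binormal separation; true AUC = pnorm(mu / sqrt(2))
  true_auc <- pnorm(mu / sqrt(2))
  n <- 400
  cover <- vapply(1:300, function(i) {
    y <- rep(0:1, each = n / 2)
    s <- c(rnorm(n / 2), rnorm(n / 2, mu))
    ci <- delong_ci(s, y)$ci
    ci[1] <= true_auc && true_auc <= ci[2]
  }, TRUE)
  expect_equal(mean(cover), 0.95, tolerance = 0.035)
})

test_that("paired DeLong test: self-comparison and rank invariance give p = 1", {
  set.seed(55)
  s <- rnorm(30); y <- rbinom(30, 1, 0.5); y[1:4] <- c(0, 0, 1, 1)
  expect_equal(delong_paired_test(s, s, y)$p, 1)
  r <- delong_paired_test(s, plogis(s), y)   # monotone transform, equal AUCs
  expect_equal(r$auc1, r$auc2)
  expect_equal(r$p, 1)
})

test_that("paired DeLong variance agrees with a bootstrap resampling reference", {
  set.seed(56)
  n <- 120
  y <- rep(0:1, each = n / 2)
  s1 <- rnorm(n) + y * 1.0
  s2 <- 0.6 * s1 + rnorm(n, 0, 0.8)
  r <- delong_paired_test(s1, s2, y)
  vd_analytic <- ((r$auc1 - r$auc2) / r$z)^2
  # nonparametric bootstrap of the paired AUC difference
  B <- 1500
  d_boot <- vapply(1:B, function(b) {
    i <- c(sample(which(y == 0), n / 2, TRUE),
           sample(which(y == 1), n / 2, TRUE))
    auc(s1[i], y[i])$auc - auc(s2[i], y[i])$auc
  }, 0)
  expect_equal(vd_analytic, stats::var(d_boot), tolerance = 0.25)
  # and the resulting normal p-values agree
  p_boot <- 2 * stats::pnorm(-abs((r$auc1 - r$auc2) / stats::sd(d_boot)))
  expect_lt(abs(r$p - p_boot), 0.05)
})

test_that("Youden operating point matches the exhaustive threshold sweep", {
  # hand-checkable example
  op <- youden_operating_point(c(0.9, 0.4, 0.5, 0.3), c(1, 1, 0, 0))
  cand <- sort(unique(c(0.9, 0.4, 0.5, 0.3)))
  best_J <- max(vapply(cand, function(t) {
    pred <- c(0.9, 0.4, 0.5, 0.3) >= t
    mean(pred[1:2]) + mean(!pred[3:4]) - 1
  }, 0))
  expect_equal(op$youden, best_J)
  # random instances against the same oracle
  set.seed(57)
  for (i in 1:20) {
    s <- round(runif(20), 2); y <- rbinom(20, 1, 0.5); y[1:2] <- 0:1
    op <- youden_operating_point(s, y)
    oracle <- max(vapply(sort(unique(s)), function(t)
      mean(s[y == 1] >= t) + mean(s[y == 0] < t) - 1, 0))
    expect_equal(op$youden, oracle, tolerance = 1e-12)
  }
  # separated and degenerate inputs
  op1 <- youden_operating_point(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(c(op1$sensitivity, op1$specificity, op1$accuracy), c(1, 1, 1))
  op0 <- youden_operating_point(rep(0.5, 8), rep(0:1, 4))
  expect_equal(op0$youden, 0)
  expect_true(op0$degenerate)
})

test_that("decision curves match hand-counted net benefit", {
  # toy set: N = 10, prevalence 0.3
  probs <- c(0.9, 0.8, 0.7, 0.6, 0.5, 0.4, 0.3, 0.2, 0.1, 0.05)
  y <- c(1, 1, 0, 1, 0, 0, 0, 0, 0, 0)
  dc <- decision_curve(probs, y, thresholds = c(0.25, 0.55, 0.75))
  # pt = 0.25: predict positive for probs >= 0.25 -> TP = 3, FP = 4
  expect_equal(dc$nb_model[1], 3 / 10 - 4 / 10 * 0.25 / 0.75, tolerance = 1e-12)
  # pt = 0.55: predicted positive {0.9, 0.8, 0.7, 0.6} -> TP = 3, FP = 1
  expect_equal(dc$nb_model[2], 3 / 10 - 1 / 10 * 0.55 / 0.45, tolerance = 1e-12)
  # pt = 0.75: predicted positive {0.9, 0.8} -> TP = 2, FP = 0
  expect_equal(dc$nb_model[3], 2 / 10, tolerance = 1e-12)
  expect_true(all(dc$nb_none == 0))
  # treat-all crosses zero exactly at pt = prevalence
  dc2 <- decision_curve(probs, y, thresholds = 0.3)
  expect_equal(dc2$nb_all, 0, tolerance = 1e-12)
  # a perfect classifier attains NB = prevalence below the lowest positive
  dcp <- decision_curve(c(0.9, 0.95, 0.85, 0.1, 0.2, 0.1, 0.15, 0.1, 0.2, 0.1),
                        c(1, 1, 1, 0, 0, 0, 0, 0, 0, 0),
                        thresholds = seq(0.25, 0.8, by = 0.05))
  expect_true(all(abs(dcp$nb_model - 0.3) < 1e-12))
  # model never beats the perfect classifier
  set.seed(58)
  pr <- runif(50); yy <- rbinom(50, 1, pr)
  if (length(unique(yy)) == 2) {
    dcr <- decision_curve(pr, yy)
    expect_true(all(dcr$nb_model <= mean(yy) + 1e-12))
  }
  expect_error(decision_curve(probs, y, thresholds = c(0, 0.5)), "strictly")
})

test_that("Hosmer-Lemeshow: zero statistic when groups are perfectly calibrated", {
  # two clusters whose observed frequencies equal their mean probabilities
  probs <- c(rep(0.2, 10), rep(0.8, 10))
  y <- c(rep(1, 2), rep(0, 8), rep(1, 8), rep(0, 2))
  hl <- suppressWarnings(hosmer_lemeshow(probs, y, n_groups = 2))
  expect_equal(hl$statistic, 0, tolerance = 1e-12)
  expect_equal(hl$p, 1)
})

test_that("Hosmer-Lemeshow matches the direct two-group formula", {
  probs <- c(rep(0.3, 12), rep(0.7, 12))
  y <- c(rep(1, 5), rep(0, 7), rep(1, 10), rep(0, 2))
  hl <- suppressWarnings(hosmer_lemeshow(probs, y, n_groups = 2))
  E1 <- 12 * 0.3; E2 <- 12 * 0.7
  ref <- (5 - E1)^2 / (E1 * (1 - 0.3)) + (10 - E2)^2 / (E2 * (1 - 0.7))
  expect_equal(hl$statistic, ref, tolerance = 1e-10)
})

test_that("bootstrap calibration MAE is small for well-calibrated predictions", {
  set.seed(59)
  p <- runif(5000, 0.05, 0.95)
  y <- rbinom(5000, 1, p)
  r <- calibration_mae_bootstrap(p, y, B = 150, seed = 7)
  expect_lt(r$mae, 0.03)
  r2 <- calibration_mae_bootstrap(p, y, B = 150, seed = 7)
  expect_identical(r$mae, r2$mae)    # deterministic given seed
  # constant probabilities: flagged, degenerate single-point curve
  expect_warning(rc <- calibration_mae_bootstrap(rep(1, 100), rep(1, 100),
                                                 B = 100, seed = 1),
                 "constant")
  expect_equal(rc$mae, 0)
  expect_error(calibration_mae_bootstrap(p, y, B = 10, seed = 1), "at least")
})

test_that("cohort balance tests follow the stated conventions", {
  # identical samples -> p = 1 under the tie-corrected approximation
  r <- cohort_balance_tests(c(1, 2, 3, 4), c(1, 2, 3, 4), "continuous")
  expect_equal(r$p, 1)
  # disjoint supports
  r2 <- cohort_balance_tests(1:20, 101:120, "continuous")
  expect_lt(r2$p, 0.001)
  # 2x2 chi-square equals the hand formula on (20,10;10,20)
  gA <- rep(c("x", "y"), c(20, 10)); gB <- rep(c("x", "y"), c(10, 20))
  r3 <- cohort_balance_tests(gA, gB, "categorical")
  tab <- rbind(c(20, 10), c(10, 20))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  expect_equal(r3$statistic, sum((tab - E)^2 / E), tolerance = 1e-10)
  expect_identical(r3$method, "chi-square")
  # sparse cells switch to Fisher's exact test
  r4 <- cohort_balance_tests(rep(c("x", "y"), c(2, 8)),
                             rep(c("x", "y"), c(7, 1)), "categorical")
  expect_identical(r4$method, "fisher")
})
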