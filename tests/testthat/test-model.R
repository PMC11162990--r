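test_that("LASSO selection finds the informative column and is reproducible", {
  set.seed(17)
  n <- 200
  y <- rep(0:1, each = n / 2)
  X <- matrix(rnorm(n * 10), n, 10,
              dimnames = list(NULL, paste0("f", 1:10)))
  X[, 4] <- y + rnorm(n, 0, 0.3)      # monotone in the label, plus noise
  s1 <- lasso_select(X, y, seed = 3)
  s2 <- lasso_select(X, y, seed = 3)
  expect_true("f4" %in% s1$selected)
  expect_identical(s1$selected, s2$selected)
  expect_identical(s1$lambda, s2$lambda)
  expect_error(lasso_select(X, rep(1, n)), "both classes")
  expect_error(lasso_select(X[1:15, ], rep(0:1, length.out = 15)), "n >= 2")
})

test_that("at full shrinkage the selection is empty", {
  set.seed(18)
  n <- 100
  y <- rep(0:1, each = 50)
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  Xs <- scale(X)
  lam_max <- max(abs(crossprod(Xs, y - mean(y)))) / n
  fit <- glmnet::glmnet(Xs, y, family = "binomial", standardize = FALSE)
  cf <- as.matrix(stats::coef(fit, s = lam_max * 1.05))
  expect_identical(sum(cf[-1L, 1L] != 0), 0L)
})

test_that("logistic closed forms: intercept-only and 2x2 log odds ratio", {
  m0 <- fit_logistic(matrix(nrow = 10, ncol = 0), c(rep(1, 3), rep(0, 7)))
  expect_equal(m0$intercept, log(0.3 / 0.7), tolerance = 1e-8)
  # 2x2 table (a,b;c,d) = (20,10;10,20): slope = log(ad/bc) = log 4
  x <- matrix(c(rep(1, 30), rep(0, 30)), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- c(rep(1, 20), rep(0, 10), rep(1, 10), rep(0, 20))
  m1 <- fit_logistic(x, y)
  expect_equal(unname(m1$coefficients), log(4), tolerance = 1e-6)
  expect_false(m1$separation)
  pr <- predict_model(m1, x)
  expect_true(all(pr > 0 & pr < 1))
})

test_that("Wald p-values are approximately uniform under the null", {
  set.seed(23)
  ps <- replicate(60, {
    n <- 500
    y <- rbinom(n, 1, 0.4)
    X <- matrix(rnorm(n), ncol = 1, dimnames = list(NULL, "x"))
    fit_logistic(X, y)$p_values
  })
  expect_equal(mean(ps < 0.05), 0.05, tolerance = 0.05)
  expect_equal(mean(ps), 0.5, tolerance = 0.1)
})

test_that("perfect separation falls back to a flagged ridge fit", {
  x <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1,
              dimnames = list(NULL, "x"))
  y <- rep(0:1, each = 20)
  expect_warning(m <- fit_logistic(x, y), "separation")
  expect_true(m$separation)
  expect_true(is.finite(m$coefficients) && m$coefficients > 0)
})

test_that("significant_features thresholds Wald p-values", {
  m <- structure(list(p_values = c(a = 0.04, b = 0.5, c = 0.049, d = 0.051)),
                 class = "diagnostic_model")
  expect_identical(significant_features(m), c("a", "c"))
  m$p_values[] <- 0.5
  expect_length(significant_features(m), 0L)
})

test_that("Spearman correlation: monotone invariance and the rank formula", {
  x <- c(0.3, 1.1, 2.2, 3.5, 4.1)
  expect_equal(spearman_rho(x, exp(x)), 1)
  expect_equal(spearman_rho(x, -x), -1)
  # worked 5-point example: d^2 = (1,1,1,1,0), 1 - 6*4/120 = 0.8
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)), 1 - 6 * 4 / (5 * 24))
  expect_equal(spearman_rho(1:5, c(2, 1, 4, 3, 5)),
               cor(1:5, c(2, 1, 4, 3, 5), method = "spearman"))
  expect_warning(v <- spearman_rho(rep(1, 5), 1:5), "zero rank variance")
  expect_true(is.na(v))
})

test_that("redundancy pruning drops the lower-ICC member of correlated pairs", {
  set.seed(41)
  n <- 60
  a <- rnorm(n)
  M <- cbind(a = a, b = a + rnorm(n, 0, 1e-6), c = rnorm(n))
  icc <- c(a = 0.95, b = 0.90, c = 0.85)
  ps <- prune_redundant(colnames(M), M, icc)
  expect_identical(sort(ps$kept), c("a", "c"))
  expect_identical(ps$audit$dropped, "b")
  # nothing to drop when all |rho| <= threshold
  M2 <- cbind(a = rnorm(n), b = rnorm(n))
  ps2 <- prune_redundant(colnames(M2), M2, c(a = 0.9, b = 0.9))
  expect_identical(sort(ps2$kept), c("a", "b"))
  expect_error(prune_redundant(c("a", "zz"), M, icc), "zz")
})

test_that("pruning survivors satisfy the threshold (exhaustive-search check)", {
  set.seed(42)
  n <- 80
  base <- rnorm(n)
  M <- cbind(a = base + rnorm(n, 0, 0.3),
             b = base + rnorm(n, 0, 0.3),
             c = base + rnorm(n, 0, 0.3))
  icc <- c(a = 0.92, b = 0.88, c = 0.95)
  ps <- prune_redundant(colnames(M), M, icc, rho_threshold = 0.70)
  ok_set <- function(keep) {
    if (length(keep) < 2) return(TRUE)
    cmb <- utils::combn(keep, 2)
    all(apply(cmb, 2, function(pr)
      abs(spearman_rho(M[, pr[1]], M[, pr[2]])) <= 0.70))
  }
  expect_true(ok_set(ps$kept))
  # brute force: no admissible subset with higher total ICC is larger
  subsets <- unlist(lapply(1:3, function(k)
    utils::combn(colnames(M), k, simplify = FALSE)), recursive = FALSE)
  best_size <- max(vapply(subsets[vapply(subsets, ok_set, TRUE)], length, 0L))
  expect_gte(length(ps$kept), best_size - 1L)  # greedy is near-optimal here
  expect_identical(length(ps$kept), best_size) # and optimal on this instance
})

test_that("the combined model is a logistic refit on the pruned pool", {
  set.seed(43)
  n <- 300
  y <- rep(0:1, each = n / 2)
  X <- cbind(u = y + rnorm(n, 0, 0.8), v = y + rnorm(n, 0, 0.8),
             w = rnorm(n))
  icc <- c(u = 0.9, v = 0.95, w = 0.85)
  cm <- build_combined_model(c("u", "v"), X, icc, y)
  expect_true(all(c("u", "v") %in% cm$model$features))
  expect_true(all(cm$model$p_values[c("u", "v")] < 0.05))
  # single surviving feature equals the univariate fit
  cm1 <- build_combined_model("u", X, icc, y)
  uni <- fit_logistic(X[, "u", drop = FALSE], y)
  expect_equal(cm1$model$coefficients, uni$coefficients, tolerance = 1e-10)
  expect_error(build_combined_model(character(0), X, icc, y), "empty")
})
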