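test_that("percentile uses closest-ranks linear interpolation", {
  expect_equal(percentile(c(1, 2, 3, 4, 5), 50), 3)
  expect_equal(percentile(c(1, 2, 3, 4, 5), 10), 1.4)
  expect_equal(percentile(7, 30), 7)
  expect_error(percentile(numeric(0), 50), "empty")
  expect_error(percentile(1:3, 120), "0, 100")
})

test_that("discretization produces bin probabilities", {
  p <- discretize(rep(3.3, 10), 64)
  expect_equal(sum(p), 1)
  expect_equal(sum(p > 0), 1L)
  expect_equal(discretize(seq(0, 63), 64), rep(1 / 64, 64))
  expect_equal(discretize(c(0, 0, 1, 1, 1, 2), 3), c(1 / 3, 1 / 2, 1 / 6))
})

test_that("the first-order set has 18 features with the documented values", {
  expect_length(first_order_names(), 18L)
  fv <- extract_first_order(c(1, 2, 3, 4, 5))
  expect_named(fv, paste0(first_order_names()))
  expect_equal(unname(fv["mean"]), 3)
  expect_equal(unname(fv["median"]), 3)
  expect_equal(unname(fv["skewness"]), 0)
  expect_equal(unname(fv["range"]), 4)
  expect_equal(unname(fv["variance"]), 2)     # population moments
  # constant input
  fc <- extract_first_order(rep(4.2, 9))
  expect_equal(unname(fc[c("uniformity", "entropy", "skewness", "variance")]),
               c(1, 0, 0, 0))
  # direct moment-summation oracle on an asymmetric sample
  x <- c(1, 1, 2, 8)
  m <- mean(x); m2 <- mean((x - m)^2); m3 <- mean((x - m)^3)
  fo <- extract_first_order(x)
  expect_equal(unname(fo["skewness"]), m3 / m2^1.5)
  expect_equal(unname(fo["energy"]), 70)
  expect_equal(unname(fo["kurtosis"]), mean((x - m)^4) / m2^2)
  expect_error(extract_first_order(numeric(0)), "empty")
})

test_that("kurtosis of a large normal sample approaches 3 (non-excess)", {
  set.seed(2)
  fv <- extract_first_order(rnorm(2e5))
  expect_equal(unname(fv["kurtosis"]), 3, tolerance = 0.05)
})

test_that("affine equivariance and the total-energy identity hold", {
  set.seed(11)
  x <- rgamma(500, 2, 1)
  a <- 2.5; cshift <- 7
  f1 <- extract_first_order(x, voxel_volume = 3.2)
  f2 <- extract_first_order(a * x + cshift, voxel_volume = 3.2)
  for (nm in c("mean", "median", "10P", "90P", "min", "max"))
    expect_equal(unname(f2[nm]), a * unname(f1[nm]) + cshift, tolerance = 1e-12)
  expect_equal(unname(f2["variance"]), a^2 * unname(f1["variance"]),
               tolerance = 1e-12)
  expect_equal(unname(f2["skewness"]), unname(f1["skewness"]), tolerance = 1e-10)
  expect_equal(unname(f2["kurtosis"]), unname(f1["kurtosis"]), tolerance = 1e-10)
  expect_equal(unname(f1["TE"]), 3.2 * unname(f1["energy"]), tolerance = 1e-12)
  expect_gte(unname(f1["entropy"]), 0)
  expect_true(f1["uniformity"] > 0 && f1["uniformity"] <= 1)
})

test_that("a participant yields exactly 14 x 18 = 252 features", {
  shape <- c(6, 6, 4)
  mask <- array(FALSE, shape); mask[2:5, 2:5, 2:3] <- TRUE
  truth <- sample_parameter_maps(group_param_spec(), shape, mask, seed = 3)
  fv <- participant_features(truth, mask)
  expect_length(fv, 252L)
  expect_true(all(grepl("^(ADC|IVIM|DKI|SEM|FROC|CTRW)", names(fv))))
  # constant maps -> all skewness 0, all uniformity 1
  const <- param_map_set(lapply(stats::setNames(metric_catalog()$map,
                                                metric_catalog()$map),
                                function(nm) array(1, shape)))
  fc <- participant_features(const, mask)
  expect_true(all(fc[grepl("-skewness$", names(fc))] == 0))
  expect_true(all(fc[grepl("-uniformity$", names(fc))] == 1))
})

test_that("the feature table is deterministic with stable column order", {
  shape <- c(6, 6, 4)
  mask <- array(FALSE, shape); mask[2:5, 2:5, 2:3] <- TRUE
  truth <- sample_parameter_maps(group_param_spec(), shape, mask, seed = 9)
  tab <- build_feature_table(list(truth, truth), list(mask, mask), c(0, 1))
  expect_identical(dim(tab), c(2L, 254L))   # id + label + 252
  expect_identical(unname(unlist(tab[1, -(1:2)])),
                   unname(unlist(tab[2, -(1:2)])))
  # missing map -> participant-level error naming the gap
  partial <- truth; partial$maps[["CTRW-D"]] <- NULL
  class(partial) <- "param_map_set"
  expect_error(build_feature_table(list(partial), list(mask), 1), "P001")
})
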