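shape <- c(10, 10, 8)
mk <- ellipsoid_mask(shape, center = c(5.5, 5.5, 4.5), radii = c(3.5, 3, 2.5))

test_that("truth-map sampling respects the spec and is seed-deterministic", {
  sp <- group_param_spec()
  t1 <- sample_parameter_maps(sp, shape, mk$mask, seed = 4)
  t2 <- sample_parameter_maps(sp, shape, mk$mask, seed = 4)
  expect_identical(t1$maps, t2$maps)
  expect_length(t1$maps, 14L)
  expect_true(all(is.na(t1$maps[["CTRW-D"]][!mk$mask])))
  # zero-variance spec -> constant maps at the location parameter
  sp0 <- sp; sp0$between_sd <- 0; sp0$within_sd <- 0
  t0 <- sample_parameter_maps(sp0, shape, mk$mask, seed = 4, smooth = 0L)
  for (r in seq_len(nrow(sp0)))
    expect_equal(unique(t0$maps[[sp0$map[r]]][mk$mask]), sp0$mean[r],
                 tolerance = 1e-12)
  expect_error(group_param_spec(list(bogus = list(mean = 1))), "unknown map")
})

test_that("sampled map means match the generative location at large n", {
  big <- c(30, 30, 12)
  mask <- array(TRUE, big)     # > 1e4 voxels
  sp <- group_param_spec()
  sp$between_sd <- 0           # isolate the voxel-level distribution
  tt <- sample_parameter_maps(sp, big, mask, seed = 8, smooth = 0L)
  for (nm in c("CTRW-D", "IVIM-f", "DKI-K")) {
    r <- match(nm, sp$map)
    se <- sp$within_sd[r] / sqrt(sum(mask))
    expect_lt(abs(mean(tt$maps[[nm]][mask]) - sp$mean[r]), 4 * se)
  }
  # the skew mixture induces positive skewness
  sps <- sp; i <- match("CTRW-D", sp$map)
  sps$skew_w[i] <- 0.25; sps$skew_shift[i] <- 3
  ts <- sample_parameter_maps(sps, big, mask, seed = 8, smooth = 0L)
  v <- ts$maps[["CTRW-D"]][mask]
  expect_gt(mean((v - mean(v))^3) / sd(v)^3, 0.3)
})

test_that("rendered signal equals the forward model voxel-by-voxel", {
  sp <- group_param_spec()
  truth <- sample_parameter_maps(sp, shape, mk$mask, seed = 6)
  sch <- default_scheme()
  vol <- render_signal(truth, sch, "CTRW")
  vx <- which(mk$mask, arr.ind = TRUE)[1, ]
  par <- c(S0 = 100,
           D = truth$maps[["CTRW-D"]][vx[1], vx[2], vx[3]] / 1e3,
           alpha = truth$maps[["CTRW-alpha"]][vx[1], vx[2], vx[3]],
           beta = truth$maps[["CTRW-beta"]][vx[1], vx[2], vx[3]])
  expect_equal(vol[vx[1], vx[2], vx[3], ], signal_model("CTRW", par, sch),
               tolerance = 1e-10)
  # alpha = beta = 1 reduces the whole volume to the mono-exponential render
  tr <- truth
  tr$maps[["CTRW-alpha"]][] <- ifelse(is.na(tr$maps[["CTRW-alpha"]]), NA, 1)
  tr$maps[["CTRW-beta"]][] <- ifelse(is.na(tr$maps[["CTRW-beta"]]), NA, 1)
  v1 <- render_signal(tr, sch, "CTRW")
  tr$maps[["ADC"]] <- tr$maps[["CTRW-D"]]
  v2 <- render_signal(tr, sch, "ADC")
  expect_equal(v1, v2, tolerance = 1e-12)
  expect_error(render_signal(param_map_set(truth$maps["ADC"],
                                           require_full = FALSE),
                             sch, "CTRW"), "missing map")
})

test_that("Rician noise has the documented law and determinism", {
  vol <- array(50, c(20, 20, 10))
  n1 <- add_rician_noise(vol, snr = 50, seed = 9)
  n2 <- add_rician_noise(vol, snr = 50, seed = 9)
  expect_identical(n1, n2)
  # infinite SNR leaves the data untouched
  expect_equal(add_rician_noise(vol, snr = 1e12, seed = 9), vol,
               tolerance = 1e-6)
  # zero signal: Rayleigh mean sigma * sqrt(pi/2)
  z <- add_rician_noise(array(0, c(50, 50, 40)), snr = 50, seed = 10,
                        s0_ref = 100)
  sigma <- 100 / 50
  expect_equal(mean(z), sigma * sqrt(pi / 2), tolerance = 0.01)
  expect_error(add_rician_noise(vol, snr = -1, seed = 1), "positive")
})

test_that("second-rater masks stay within the Dice floor", {
  m0 <- perturb_mask(mk$mask, seed = 12, magnitude = 0)
  expect_identical(m0, mk$mask > 0)
  set.seed(99)
  for (s in 1:10) {
    mb <- perturb_mask(mk$mask, seed = s)
    dice <- 2 * sum(mb & mk$mask) / (sum(mb) + sum(mk$mask))
    expect_gte(dice, 0.85)
    expect_lte(dice, 1)
  }
  expect_identical(perturb_mask(mk$mask, seed = 3),
                   perturb_mask(mk$mask, seed = 3))
})

test_that("cohort generation is deterministic and structured", {
  c1 <- generate_cohort(3, 2, seed = 21)
  c2 <- generate_cohort(3, 2, seed = 21)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$patients[[1]]$truth$maps, c2$patients[[1]]$truth$maps)
  expect_identical(nrow(c1$manifest), 10L)
  expect_identical(sum(c1$manifest$cohort == "testing"), 4L)
  expect_true(all(vapply(c1$patients, function(p) sum(p$mask) > 0, TRUE)))
  expect_error(generate_cohort(1, 1, seed = 1), "at least 2")
})

test_that("noiseless render -> volume fit closes the loop on the truth maps", {
  small <- c(6, 6, 5)
  msk <- array(FALSE, small); msk[2:4, 2:4, 2:3] <- TRUE
  sp <- group_param_spec()
  truth <- sample_parameter_maps(sp, small, msk, seed = 31)
  sch <- default_scheme()
  vol <- render_signal(truth, sch, "SEM")
  fm <- fit_volume("SEM", vol, msk, sch)
  for (nm in c("SEM-DDC", "SEM-alpha")) {
    rel <- abs(fm$maps[[nm]][msk] - truth$maps[[nm]][msk]) /
      truth$maps[[nm]][msk]
    expect_lt(max(rel), 1e-3)
  }
})
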