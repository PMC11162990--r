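#' Per-class generative specification of the truth parameter maps
#'
#' Describes, for each of the 14 metric maps, how a patient's ground-truth
#' values are drawn: a patient-level map mean (normal with `between_sd`
#' across patients), voxel-level scatter (`within_sd`), and an optional
#' one-sided mixture component (`skew_w`, `skew_shift` in units of
#' `within_sd`) that induces within-tumor right-skew. Values are clipped to
#' the physiologic fitting bounds. Map units are the display units of
#' [metric_catalog()] (diffusivities in 1e-3 mm^2/s).
#'
#' The defaults emulate a non-muscle-invasive-like (class 0) bladder-tumor
#' tissue profile; [spec_mibc_like()] and [spec_hg_like()] derive the
#' contrasted classes the study reports: lower tissue diffusivity plus
#' higher within-tumor skewness for the muscle-invasive-like class, and a
#' higher perfusion fraction for the high-grade-like class.
#'
#' @param overrides named list of per-map overrides; each entry may set
#'   `mean`, `between_sd`, `within_sd`, `skew_w`, `skew_shift`.
#' @return data.frame of class `group_param_spec`, one row per map.
#' @export
group_param_spec <- function(overrides = list()) {
  cat <- metric_catalog()
  base <- data.frame(
    map = cat$map,
    mean = c(1.5,               # ADC (1e-3 mm^2/s)
             0.10, 1.2, 15,     # IVIM f, D, D*
             0.7, 1.8,          # DKI K, D
             0.85, 1.5,         # SEM alpha, DDC
             0.85, 8, 1.3,      # FROC beta, mu (um), D
             0.85, 0.85, 1.3),  # CTRW alpha, beta, D
    between_sd = c(0.12, 0.015, 0.10, 1.5, 0.06, 0.14, 0.03, 0.12,
                   0.03, 0.8, 0.10, 0.03, 0.03, 0.10),
    within_sd = c(0.15, 0.02, 0.12, 2.0, 0.08, 0.18, 0.04, 0.15,
                  0.04, 1.0, 0.12, 0.04, 0.04, 0.12),
    skew_w = 0, skew_shift = 0,
    stringsAsFactors = FALSE)
  for (nm in names(overrides)) {
    i <- match(nm, base$map)
    if (is.na(i)) stop("unknown map in overrides: ", nm)
    for (fld in names(overrides[[nm]])) base[i, fld] <- overrides[[nm]][[fld]]
  }
  class(base) <- c("group_param_spec", "data.frame")
  base
}

d_like_maps <- function()
  c("ADC", "IVIM-D", "DKI-D", "SEM-DDC", "FROC-D", "CTRW-D")

#' @rdname group_param_spec
#' @param d_scale multiplicative contrast on the diffusivity-map means
#'   (0.7 = the 30% reduction used for the muscle-invasive-like class).
#' @param skew_w,skew_shift mixture weight and shift applied to the
#'   diffusivity and exponent maps of the contrasted class.
#' @export
spec_mibc_like <- function(d_scale = 0.7, skew_w = 0.25, skew_shift = 3) {
  sp <- group_param_spec()
  dm <- sp$map %in% d_like_maps()
  sp$mean[dm] <- sp$mean[dm] * d_scale
  skewed <- sp$map %in% c(d_like_maps(), "CTRW-alpha", "SEM-alpha")
  sp$skew_w[skewed] <- skew_w
  sp$skew_shift[skewed] <- skew_shift
  sp
}

#' @rdname group_param_spec
#' @param f_shift additive shift on the perfusion-fraction mean for the
#'   high-grade-like class.
#' @export
spec_hg_like <- function(f_shift = 0.05, d_scale = 0.8) {
  sp <- group_param_spec()
  i <- match("IVIM-f", sp$map)
  sp$mean[i] <- sp$mean[i] + f_shift
  dm <- sp$map %in% d_like_maps()
  sp$mean[dm] <- sp$mean[dm] * d_scale
  sp
}

# physiologic clip range per map, in display units
map_clip_range <- function(map) {
  switch(map,
    "IVIM-f" = c(0.005, 0.5),
    "DKI-K" = c(0.01, 3),
    "SEM-alpha" = , "FROC-beta" = , "CTRW-alpha" = , "CTRW-beta" = c(0.3, 1),
    "IVIM-Dstar" = c(3.5, 100),
    "FROC-mu" = c(0.5, 20),
    c(0.05, 5))   # diffusivities, 1e-3 mm^2/s
}

#' Sample ground-truth parameter maps for one patient
#'
#' @param spec a [group_param_spec].
#' @param shape length-3 grid dimensions.
#' @param mask 3D VOI mask on that grid.
#' @param seed integer seed (full determinism).
#' @param voxel_size mm per axis.
#' @param smooth number of 6-neighbour in-mask smoothing passes.
#' @return a [param_map_set] with truth values on the mask (NA outside).
#' @export
sample_parameter_maps <- function(spec, shape, mask, seed,
                                  voxel_size = c(1, 1, 1), smooth = 1L) {
  idx <- which(mask > 0)
  if (length(idx) == 0L) stop("mask is empty")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  maps <- list()
  for (r in seq_len(nrow(spec))) {
    row <- spec[r, ]
    pmean <- stats::rnorm(1, row$mean, row$between_sd)
    vals <- stats::rnorm(length(idx), pmean, row$within_sd)
    if (row$skew_w > 0) {
      hit <- stats::runif(length(idx)) < row$skew_w
      vals[hit] <- vals[hit] + abs(row$skew_shift) * row$within_sd
    }
    cl <- map_clip_range(row$map)
    arr <- array(NA_real_, shape)
    arr[idx] <- pmin(pmax(vals, cl[1L]), cl[2L])
    if (smooth > 0L) arr <- smooth_in_mask(arr, mask, smooth)
    maps[[row$map]] <- arr
  }
  param_map_set(maps, voxel_size = voxel_size)
}

smooth_in_mask <- function(arr, mask, passes = 1L) {
  d <- dim(arr)
  for (p in seq_len(passes)) {
    acc <- array(0, d); cnt <- array(0, d)
    ok <- is.finite(arr) & mask > 0
    add <- function(sh) {
      src <- shift_array(arr, sh); oks <- shift_array(ok, sh)
      use <- ok & !is.na(oks) & oks
      acc[use] <<- acc[use] + src[use]
      cnt[use] <<- cnt[use] + 1
    }
    add(c(0, 0, 0))
    for (ax in 1:3) for (s in c(-1L, 1L)) {
      sh <- integer(3); sh[ax] <- s; add(sh)
    }
    new <- arr
    new[cnt > 0] <- acc[cnt > 0] / cnt[cnt > 0]
    arr <- new
  }
  arr
}

shift_array <- function(a, sh) {
  d <- dim(a)
  out <- array(NA, d)
  src <- lapply(1:3, function(ax) {
    i <- seq_len(d[ax]) + sh[ax]
    i[i < 1 | i > d[ax]] <- NA
    i
  })
  ok <- lapply(src, function(i) !is.na(i))
  out[ok[[1L]], ok[[2L]], ok[[3L]]] <-
    a[src[[1L]][ok[[1L]]], src[[2L]][ok[[2L]]], src[[3L]][ok[[3L]]]]
  out
}

#' Render the noiseless DWI volume implied by truth maps
#'
#' Per-voxel forward evaluation of the chosen generator model's signal
#' equation over the scheme, using that model's truth maps (converted from
#' display units back to mm^2/s).
#'
#' @param truth a [param_map_set] (may be partial, but must contain the
#'   generator model's maps).
#' @param scheme a [bval_scheme].
#' @param generator_model one of `"ADC"`, `"IVIM"`, `"DKI"`, `"SEM"`,
#'   `"FROC"`, `"CTRW"`.
#' @param S0 b = 0 signal (same for all voxels).
#' @return 4D array (grid x b); 0 outside the truth support.
#' @export
render_signal <- function(truth, scheme, generator_model, S0 = 100) {
  cat_rows <- metric_catalog()[metric_catalog()$model == generator_model, ]
  miss <- setdiff(cat_rows$map, names(truth$maps))
  if (length(miss))
    stop("truth is missing map(s): ", paste(miss, collapse = ", "))
  b <- as_b(scheme)
  shape <- dim(truth$maps[[1L]])
  idx <- which(is.finite(truth$maps[[cat_rows$map[1L]]]))
  vol <- array(0, c(shape, length(b)))
  pv <- matrix(NA_real_, length(idx), nrow(cat_rows),
               dimnames = list(NULL, cat_rows$param))
  for (r in seq_len(nrow(cat_rows)))
    pv[, r] <- truth$maps[[cat_rows$map[r]]][idx] / cat_rows$scale[r]
  nvox <- prod(shape)
  for (j in seq_along(idx)) {
    par <- c(S0 = S0, pv[j, ])
    sig <- fwd_signal(generator_model, par[model_param_names(generator_model)],
                      scheme, b)
    vol[idx[j] + (seq_along(b) - 1L) * nvox] <- sig
  }
  vol
}

#' Add Rician noise to a magnitude volume
#'
#' Each value S is replaced by \eqn{\sqrt{(S+\sigma\epsilon_1)^2 +
#' (\sigma\epsilon_2)^2}} with independent standard-normal noise and
#' \eqn{\sigma = S_{0,ref}/SNR}.
#'
#' @param volume numeric array.
#' @param snr signal-to-noise ratio referenced to `s0_ref`.
#' @param seed integer seed.
#' @param s0_ref reference b = 0 signal defining sigma.
#' @param gaussian if TRUE, add plain Gaussian noise instead (debugging).
#' @return noisy array, same shape.
#' @export
add_rician_noise <- function(volume, snr, seed, s0_ref = 100,
                             gaussian = FALSE) {
  if (snr <= 0) stop("snr must be positive")
  sigma <- s0_ref / snr
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  e1 <- array(stats::rnorm(length(volume)), dim(volume))
  if (gaussian) return(volume + sigma * e1)
  e2 <- array(stats::rnorm(length(volume)), dim(volume))
  sqrt((volume + sigma * e1)^2 + (sigma * e2)^2)
}

#' Ellipsoid VOI mask (optionally with an interior exclusion ellipsoid)
#'
#' @param shape length-3 grid dimensions.
#' @param center ellipsoid center (voxel coordinates).
#' @param radii length-3 semi-axes in voxels.
#' @param necrosis_frac if > 0, an interior co-centered ellipsoid with
#'   semi-axes scaled by this fraction is returned as the exclusion mask.
#' @return list: `mask`, `exclusion` (NULL when `necrosis_frac` = 0).
#' @export
ellipsoid_mask <- function(shape, center, radii, necrosis_frac = 0) {
  g <- expand.grid(x = seq_len(shape[1L]), y = seq_len(shape[2L]),
                   z = seq_len(shape[3L]))
  r2 <- ((g$x - center[1L]) / radii[1L])^2 +
        ((g$y - center[2L]) / radii[2L])^2 +
        ((g$z - center[3L]) / radii[3L])^2
  mask <- array(r2 <= 1, shape)
  excl <- NULL
  if (necrosis_frac > 0)
    excl <- array(r2 <= necrosis_frac^2, shape)
  list(mask = mask, exclusion = excl)
}

#' Simulate a second rater's VOI by perturbing the boundary
#'
#' Boundary voxels (mask voxels touching background and background voxels
#' touching the mask, 6-connectivity) are independently toggled with
#' probability `magnitude`; if the Dice overlap with the original falls
#' below `dice_floor` the perturbation is retried at half magnitude, and an
#' error is raised if the mask would empty.
#'
#' @param mask 3D binary mask.
#' @param seed integer seed.
#' @param magnitude toggle probability for boundary voxels.
#' @param dice_floor minimum acceptable Dice overlap.
#' @return perturbed 3D logical mask.
#' @export
perturb_mask <- function(mask, seed, magnitude = 0.3, dice_floor = 0.85) {
  if (!any(mask > 0)) stop("mask is empty")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  m <- mask > 0
  attempt <- function(mag) {
    nb <- neighbor_count(m)
    inner_b <- m & nb < 6L          # surface of the mask
    outer_b <- !m & nb > 0L         # background shell
    cand <- which(inner_b | outer_b)
    flip <- cand[stats::runif(length(cand)) < mag]
    out <- m
    out[flip] <- !out[flip]
    out
  }
  for (mag in magnitude / 2^(0:5)) {
    out <- attempt(mag)
    if (!any(out)) next
    dice <- 2 * sum(out & m) / (sum(out) + sum(m))
    if (dice >= dice_floor) return(out)
  }
  stop("could not perturb mask while keeping Dice >= ", dice_floor)
}

neighbor_count <- function(m) {
  cnt <- array(0L, dim(m))
  for (ax in 1:3) for (s in c(-1L, 1L)) {
    sh <- integer(3); sh[ax] <- s
    nb <- shift_array(m, sh)
    nb[is.na(nb)] <- FALSE
    cnt <- cnt + nb
  }
  cnt
}

#' Generate a two-class synthetic cohort
#'
#' Independent synthetic patients with ellipsoidal tumors, ground-truth
#' parameter maps drawn from per-class specifications, a second-rater mask,
#' an optional interior necrosis exclusion, and (optionally) rendered
#' noisy DWI. Training/testing sub-cohorts get disjoint seed streams,
#' emulating the study's two-scanner design.
#'
#' @param n_per_class patients per class in the training cohort.
#' @param n_test_per_class patients per class in the testing cohort.
#' @param spec0,spec1 [group_param_spec] for class 0 / class 1.
#' @param shape grid dimensions.
#' @param radii_range tumor semi-axis range in voxels (desk-scale).
#' @param necrosis_prob probability a tumor carries an exclusion region.
#' @param scheme a [bval_scheme] (used when rendering DWI).
#' @param snr Rician SNR at b = 0 (used when rendering).
#' @param seed master integer seed.
#' @param render if TRUE, each patient also carries a noisy 4D `dwi`.
#' @param generator_model forward model used for rendering.
#' @return list of class `synthetic_cohort`: `patients` (each with `truth`,
#'   `mask`, `mask_b`, `exclusion`, `label`, `cohort`, `seed`, optional
#'   `dwi`), `manifest` (data.frame), `scheme`.
#' @export
generate_cohort <- function(n_per_class, n_test_per_class = 0L,
                            spec0 = group_param_spec(),
                            spec1 = group_param_spec(),
                            shape = c(16, 16, 12), radii_range = c(3, 6),
                            necrosis_prob = 0.3,
                            scheme = default_scheme(), snr = 50,
                            seed = 1L, render = FALSE,
                            generator_model = "CTRW") {
  if (n_per_class < 2L) stop("need at least 2 patients per class")
  plan <- rbind(
    data.frame(label = rep(c(0L, 1L), each = n_per_class), cohort = "training"),
    if (n_test_per_class > 0L)
      data.frame(label = rep(c(0L, 1L), each = n_test_per_class),
                 cohort = "testing"))
  n <- nrow(plan)
  patients <- vector("list", n)
  for (i in seq_len(n)) {
    pseed <- as.integer((as.numeric(seed) * 10007 + i * 13) %% 2147483629)
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(pseed)
    radii <- stats::runif(3, radii_range[1L], radii_range[2L])
    center <- shape / 2 + stats::runif(3, -1, 1)
    nec <- if (stats::runif(1) < necrosis_prob) 0.4 else 0
    geo <- ellipsoid_mask(shape, center, radii, necrosis_frac = nec)
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    spec <- if (plan$label[i] == 1L) spec1 else spec0
    truth <- sample_parameter_maps(spec, shape, geo$mask, seed = pseed + 1L)
    mask_b <- perturb_mask(geo$mask, seed = pseed + 2L)
    pat <- list(truth = truth, mask = geo$mask, mask_b = mask_b,
                exclusion = geo$exclusion, label = plan$label[i],
                cohort = plan$cohort[i], seed = pseed)
    if (render) {
      clean <- render_signal(truth, scheme, generator_model)
      pat$dwi <- add_rician_noise(clean, snr, seed = pseed + 3L, s0_ref = 100)
    }
    patients[[i]] <- pat
  }
  manifest <- data.frame(id = sprintf("P%03d", seq_len(n)),
                         label = plan$label, cohort = plan$cohort,
                         seed = vapply(patients, `[[`, 0, "seed"))
  structure(list(patients = patients, manifest = manifest, scheme = scheme),
            class = "synthetic_cohort")
}
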