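#' Fitting options for voxel-wise model estimation
#'
#' The study's in-house fitting software is not public, so the estimation
#' strategy is this package's own documented choice: bounded nonlinear least
#' squares (port algorithm via [stats::nlminb]), initialized from a
#' log-linear mono-exponential fit, with a segmented IVIM stage and a small
#' number of jittered restarts when the first attempt does not converge.
#'
#' @param bounds named list of `c(lower, upper)` per parameter; defaults are
#'   physiologic: ADC/D/DDC in (1e-6, 5e-3) mm^2/s, D* in (3e-3, 0.1) mm^2/s,
#'   f in [0, 0.5], K in [0, 3], alpha/beta in (0.01, 1], mu in (1e-4, 0.02) mm.
#' @param b_max_ivim IVIM uses only b-values <= this (s/mm^2) to limit
#'   kurtosis contamination at high b.
#' @param adc_b the conventional-DWI b-value pair used for the ADC map; the
#'   acquisition this package models computed ADC from b = 0 and 800 s/mm^2.
#'   Set `NULL` to use every b-value.
#' @param n_restarts jittered restarts when the initial fit fails to converge.
#' @param restart_seed base seed for restart jitter (recorded in results).
#' @param rician_sigma optional known noise level; when given, model
#'   predictions are mapped through `sqrt(S^2 + sigma^2)` before residuals
#'   are formed, a first-moment correction for the Rician noise floor.
#' @return a list of class `fit_options`.
#' @export
fit_options <- function(bounds = list(), b_max_ivim = 1000, adc_b = c(0, 800),
                        n_restarts = 3L, restart_seed = 20240609L,
                        rician_sigma = NULL, froc_mu = 5e-3) {
  def <- list(
    S0    = c(1e-9, Inf),
    ADC   = c(1e-6, 5e-3),
    D     = c(1e-6, 5e-3),
    DDC   = c(1e-6, 5e-3),
    Dstar = c(3e-3, 0.1),
    f     = c(0, 0.5),
    K     = c(0, 3),
    alpha = c(0.01, 1),
    beta  = c(0.01, 1),
    mu    = c(1e-4, 0.02))
  def[names(bounds)] <- bounds
  structure(list(bounds = def, b_max_ivim = b_max_ivim, adc_b = adc_b,
                 n_restarts = as.integer(n_restarts),
                 restart_seed = as.integer(restart_seed),
                 rician_sigma = rician_sigma, froc_mu = froc_mu),
            class = "fit_options")
}

model_param_names <- function(model) {
  switch(model,
    ADC  = c("S0", "ADC"),
    IVIM = c("S0", "f", "D", "Dstar"),
    DKI  = c("S0", "D", "K"),
    SEM  = c("S0", "DDC", "alpha"),
    FROC = c("S0", "D", "beta", "mu"),
    CTRW = c("S0", "D", "alpha", "beta"),
    stop("unknown model: ", model))
}

# unchecked forward evaluators used inside optimization (bounds handled by
# the optimizer; invariant checks would throw mid-search)
fwd_signal <- function(model, par, scheme, b) {
  switch(model,
    ADC  = par[1L] * exp(-b * par[2L]),
    IVIM = par[1L] * (par[2L] * exp(-b * par[4L]) + (1 - par[2L]) * exp(-b * par[3L])),
    DKI  = par[1L] * exp(-b * par[2L] + par[3L] * (b * par[2L])^2 / 6),
    SEM  = par[1L] * exp(-(b * par[2L])^par[3L]),
    FROC = fwd_froc(par, scheme, b),
    CTRW = par[1L] * mittag_leffler(par[3L], -(b * par[2L])^par[4L], tol = 1e-9))
}

fwd_froc <- function(par, scheme, b) {
  beta <- par[3L]
  if (abs(beta - 1) < 1e-12) return(par[1L] * exp(-b * par[2L]))
  Delta_s <- scheme$Delta * 1e-3
  delta_s <- scheme$delta * 1e-3
  gd <- scheme$gd[match(b, scheme$b)]
  texp <- Delta_s - (2 * beta - 1) / (2 * beta + 1) * delta_s
  expo <- par[2L] * par[4L]^(2 * (beta - 1)) * gd^(2 * beta) * texp
  expo[b == 0] <- 0
  par[1L] * exp(-expo)
}

loglin_adc <- function(y, b) {
  # closed-form log-linear mono-exponential fit on positive signals
  ok <- is.finite(y) & y > 0
  if (sum(ok) < 2L) return(c(S0 = max(y[1L], 1e-9), ADC = 1e-3))
  fit <- stats::lm.fit(cbind(1, -b[ok]), log(y[ok]))
  c(S0 = unname(exp(fit$coefficients[1L])), ADC = unname(fit$coefficients[2L]))
}

clip_bounds <- function(par, bounds) {
  for (nm in names(par)) {
    bb <- bounds[[nm]]
    par[nm] <- min(max(par[nm], bb[1L]), bb[2L])
  }
  par
}

#' Fit one diffusion model to a single voxel's signal decay
#'
#' @param model one of `"ADC"`, `"IVIM"`, `"DKI"`, `"SEM"`, `"FROC"`, `"CTRW"`.
#' @param signal numeric vector of magnitudes, one per b-value of `scheme`.
#' @param scheme a [bval_scheme].
#' @param options a [fit_options] list.
#' @return list with `model`, `par` (named, clipped to bounds),
#'   `residual_rms`, `converged`, `degenerate`, `n_points`, `n_restarts_used`.
#' @export
fit_voxel <- function(model, signal, scheme, options = fit_options()) {
  b_all <- as_b(scheme)
  if (length(signal) != length(b_all))
    stop("signal length (", length(signal), ") != number of b-values (",
         length(b_all), ")")
  y <- as.numeric(signal)

  # b-subset per model
  keep <- rep(TRUE, length(b_all))
  if (model == "IVIM" && !is.null(options$b_max_ivim))
    keep <- b_all <= options$b_max_ivim
  if (model == "ADC" && !is.null(options$adc_b))
    keep <- b_all %in% options$adc_b
  b <- b_all[keep]; yb <- y[keep]
  pn <- model_param_names(model)

  degen <- !any(is.finite(yb) & yb > 0) || !is.finite(yb[1L]) || yb[1L] <= 0
  if (!degen && length(b) < length(pn) + 1L && model != "ADC")
    stop("need more b-values than free parameters for ", model)
  if (degen) {
    par <- vapply(options$bounds[pn], mean, 0)
    par["S0"] <- max(mean(yb[is.finite(yb)]), 1e-9)
    names(par) <- pn
    return(list(model = model, par = par, residual_rms = NA_real_,
                converged = FALSE, degenerate = TRUE,
                n_points = sum(keep), n_restarts_used = 0L))
  }

  init <- fit_init(model, yb, b, scheme, options)
  sigma <- options$rician_sigma

  # FROC's mu is not identifiable from single-timing b-space data (only the
  # product D * mu^(2(beta-1)) enters the decay), so it is pinned to the
  # configured spatial constant and D, beta are estimated
  free <- pn
  fixed <- numeric(0)
  if (model == "FROC") {
    free <- c("S0", "D", "beta")
    fixed <- c(mu = options$froc_mu)
    init <- init[free]
  }
  full_par <- function(p) {
    out <- c(p, fixed)
    out[pn]
  }
  obj_raw <- function(p) {
    pred <- fwd_signal(model, full_par(p), scheme, b)
    if (!is.null(sigma)) pred <- sqrt(pred^2 + sigma^2)
    pen <- 0
    if (model == "IVIM" && p[4L] < 1.2 * p[3L])     # keep D* and D roles apart
      pen <- 1e4 * (1.2 * p[3L] - p[4L])^2 / p[3L]^2 * yb[1L]^2
    sum((pred - yb)^2) + pen
  }
  lower <- vapply(options$bounds[free], `[`, 0, 1L)
  upper <- vapply(options$bounds[free], `[`, 0, 2L)
  upper["S0"] <- 10 * max(yb)
  # optimize on a unit scale: parameter magnitudes span ~5 decades
  sc <- pmax(abs(init), c(S0 = max(yb), ADC = 1e-3, D = 1e-3, DDC = 1e-3,
                          Dstar = 1e-2, f = 0.1, K = 0.5, alpha = 0.5,
                          beta = 0.5, mu = 5e-3)[free] * 1e-3)
  obj <- function(ps) obj_raw(stats::setNames(ps * sc, free))

  run_nlminb <- function(p0) {
    p0 <- pmin(pmax(p0, lower), upper)
    stats::nlminb(p0 / sc, obj, lower = lower / sc, upper = upper / sc,
                  control = list(iter.max = 500L, eval.max = 1000L))
  }
  ok_msgs <- "relative convergence|absolute function convergence|X-convergence"
  best <- run_nlminb(init)
  restarts <- 0L
  if (!(best$convergence == 0 || grepl(ok_msgs, best$message)) &&
      options$n_restarts > 0L) {
    for (r in seq_len(options$n_restarts)) {
      restarts <- r
      jit <- withr_seed_jitter(init, lower, upper,
                               options$restart_seed + r)
      cand <- run_nlminb(jit)
      if (cand$objective < best$objective) best <- cand
      if (best$convergence == 0 || grepl(ok_msgs, best$message)) break
    }
  }
  par <- full_par(stats::setNames(best$par * sc, free))
  par <- clip_bounds(stats::setNames(par, pn), options$bounds)
  rms <- sqrt(max(best$objective, 0) / length(yb))
  # an exactly-interpolating fit can trip nlminb's "false convergence"
  conv <- best$convergence == 0 || grepl(ok_msgs, best$message) ||
    rms < 1e-8 * max(yb)
  list(model = model, par = par,
       residual_rms = rms,
       converged = conv,
       degenerate = FALSE,
       n_points = length(yb), n_restarts_used = restarts)
}

withr_seed_jitter <- function(init, lower, upper, seed) {
  # deterministic multiplicative jitter that respects the box
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed %% .Machine$integer.max)
  jit <- init * exp(stats::rnorm(length(init), 0, 0.2))
  pmin(pmax(jit, lower), upper)
}

fit_init <- function(model, y, b, scheme, options) {
  ll <- loglin_adc(y, b)
  S0 <- max(ll[["S0"]], 1e-9)
  D0 <- min(max(ll[["ADC"]], 2e-6), 4.9e-3)
  switch(model,
    ADC  = c(S0 = S0, ADC = D0),
    DKI  = dki_init(y, b, S0, D0),
    SEM  = c(S0 = S0, DDC = D0, alpha = 0.9),
    FROC = c(S0 = S0, D = D0, beta = 0.9, mu = options$froc_mu),
    CTRW = c(S0 = S0, D = D0, alpha = 0.9, beta = 0.9),
    IVIM = ivim_init(y, b))
}

dki_init <- function(y, b, S0, D0) {
  ok <- is.finite(y) & y > 0
  if (sum(ok) >= 3L) {
    fit <- stats::lm.fit(cbind(1, -b[ok], b[ok]^2), log(y[ok]))
    cf <- unname(fit$coefficients)
    D <- min(max(cf[2L], 2e-6), 4.9e-3)
    K <- min(max(6 * cf[3L] / D^2, 0), 3)
    c(S0 = exp(cf[1L]), D = D, K = K)
  } else c(S0 = S0, D = D0, K = 0.5)
}

ivim_init <- function(y, b) {
  # segmented: tissue D from the log-linear tail (b >= 200), then (f, D*)
  # with S0 and D held fixed; the joint bounded refinement follows in
  # fit_voxel
  hi <- b >= 200 & is.finite(y) & y > 0
  S0 <- max(y[b == 0][1L], 1e-9)
  if (sum(hi) >= 2L) {
    cf <- unname(stats::lm.fit(cbind(1, -b[hi]), log(y[hi]))$coefficients)
    D <- min(max(cf[2L], 2e-6), 4.9e-3)
    f <- min(max(1 - exp(cf[1L]) / S0, 0.01), 0.45)
  } else {
    D <- 1e-3; f <- 0.1
  }
  perf <- function(p)
    sum((S0 * (p[1L] * exp(-b * p[2L]) + (1 - p[1L]) * exp(-b * D)) - y)^2)
  st <- stats::nlminb(c(f, 15e-3), perf,
                      lower = c(0, max(3e-3, 1.5 * D)), upper = c(0.5, 0.1),
                      control = list(iter.max = 200L))
  c(S0 = S0, f = st$par[1L], D = D, Dstar = st$par[2L])
}
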