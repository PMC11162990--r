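#' Forward diffusion signal models
#'
#' Noiseless signal decays over a multi-b-value scheme for the
#' mono-exponential (ADC) model and the five non-Gaussian models. All
#' diffusivities are in mm^2/s, b-values in s/mm^2, and every model returns
#' exactly `S0` at b = 0. Each non-Gaussian model reduces to the
#' mono-exponential at its Gaussian limit: IVIM at f = 0, DKI at K = 0,
#' the stretched-exponential at alpha = 1, FROC at beta = 1 (under the
#' derived-timing convention), CTRW at alpha = beta = 1.
#'
#' @param S0 signal at b = 0 (> 0, arbitrary units).
#' @param ADC,D,DDC diffusivity in mm^2/s (> 0).
#' @param scheme a [bval_scheme] or numeric b-vector (s/mm^2).
#' @return numeric signal vector, one value per b-value.
#' @name signal_models
NULL

check_pos <- function(x, nm) {
  if (!is.finite(x) || x <= 0) stop(nm, " must be positive, got ", x)
}

#' @rdname signal_models
#' @export
signal_adc <- function(S0, ADC, scheme) {
  check_pos(S0, "S0"); check_pos(ADC, "ADC")
  if (ADC > 0.01) stop("ADC above physical range (0.01 mm^2/s)")
  S0 * exp(-as_b(scheme) * ADC)
}

#' @rdname signal_models
#' @param f perfusion (vascular volume) fraction in [0, 1].
#' @param Dstar pseudo-diffusion coefficient of the microvasculature,
#'   mm^2/s; must exceed `D`.
#' @export
signal_ivim <- function(S0, f, D, Dstar, scheme) {
  check_pos(S0, "S0"); check_pos(D, "D"); check_pos(Dstar, "Dstar")
  if (!is.finite(f) || f < 0 || f > 1) stop("f must lie in [0, 1]")
  if (Dstar <= D) stop("Dstar must exceed D")
  b <- as_b(scheme)
  S0 * (f * exp(-b * Dstar) + (1 - f) * exp(-b * D))
}

#' @rdname signal_models
#' @param K kurtosis (>= 0); K = 0 is Gaussian diffusion.
#' @export
signal_dki <- function(S0, D, K, scheme) {
  check_pos(S0, "S0"); check_pos(D, "D")
  if (!is.finite(K) || K < 0) stop("K must be >= 0")
  b <- as_b(scheme)
  S0 * exp(-b * D + K * (b * D)^2 / 6)
}

#' @rdname signal_models
#' @param alpha stretching exponent (SEM) or temporal fractional order
#'   (CTRW), in (0, 1].
#' @export
signal_sem <- function(S0, DDC, alpha, scheme) {
  check_pos(S0, "S0"); check_pos(DDC, "DDC")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  b <- as_b(scheme)
  S0 * exp(-(b * DDC)^alpha)
}

#' @rdname signal_models
#' @param beta spatial fractional order in (0, 1].
#' @param mu FROC spatial constant in mm (> 0), preserving mm^2/s units of D.
#' @export
signal_froc <- function(S0, D, beta, mu, scheme) {
  check_pos(S0, "S0"); check_pos(D, "D"); check_pos(mu, "mu")
  if (!is.finite(beta) || beta <= 0 || beta > 1)
    stop("beta must lie in (0, 1]")
  b <- as_b(scheme)
  if (beta == 1) return(S0 * exp(-b * D))
  if (!inherits(scheme, "bval_scheme") || is.null(scheme$delta))
    stop("FROC with beta != 1 needs a bval_scheme with gradient timing")
  # exponent: D * mu^(2(beta-1)) * (gamma G_d delta)^(2 beta) *
  #           (Delta - (2beta-1)/(2beta+1) * delta), timing in seconds
  Delta_s <- scheme$Delta * 1e-3
  delta_s <- scheme$delta * 1e-3
  texp <- Delta_s - (2 * beta - 1) / (2 * beta + 1) * delta_s
  expo <- D * mu^(2 * (beta - 1)) * scheme$gd^(2 * beta) * texp
  expo[b == 0] <- 0
  S0 * exp(-expo)
}

#' @rdname signal_models
#' @export
signal_ctrw <- function(S0, D, alpha, beta, scheme) {
  check_pos(S0, "S0"); check_pos(D, "D")
  if (!is.finite(alpha) || alpha <= 0 || alpha > 1)
    stop("alpha must lie in (0, 1]")
  if (!is.finite(beta) || beta <= 0 || beta > 1)
    stop("beta must lie in (0, 1]")
  b <- as_b(scheme)
  S0 * mittag_leffler(alpha, -(b * D)^beta)
}

#' Evaluate a model's forward signal from a named parameter vector
#'
#' Dispatch helper used by the fitting and phantom-rendering code.
#'
#' @param model one of `"ADC"`, `"IVIM"`, `"DKI"`, `"SEM"`, `"FROC"`, `"CTRW"`.
#' @param par named numeric vector with that model's parameters (see
#'   [signal_models]); always includes `S0`.
#' @param scheme a [bval_scheme] or numeric b-vector.
#' @return numeric signal vector.
#' @export
signal_model <- function(model, par, scheme) {
  switch(model,
    ADC  = signal_adc(par[["S0"]], par[["ADC"]], scheme),
    IVIM = signal_ivim(par[["S0"]], par[["f"]], par[["D"]], par[["Dstar"]], scheme),
    DKI  = signal_dki(par[["S0"]], par[["D"]], par[["K"]], scheme),
    SEM  = signal_sem(par[["S0"]], par[["DDC"]], par[["alpha"]], scheme),
    FROC = signal_froc(par[["S0"]], par[["D"]], par[["beta"]], par[["mu"]], scheme),
    CTRW = signal_ctrw(par[["S0"]], par[["D"]], par[["alpha"]], par[["beta"]], scheme),
    stop("unknown model: ", model))
}
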