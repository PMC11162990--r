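#' Multi-b-value acquisition scheme
#'
#' Bundles the diffusion weightings of a multi-b-value DWI acquisition with
#' the (optional) gradient-timing parameters needed by the fractional-order
#' calculus (FROC) model. When `delta`/`Delta` are supplied, the per-b-value
#' gradient factor \eqn{\gamma G_d \delta} is derived from
#' \eqn{b = (\gamma G_d \delta)^2 (\Delta - \delta/3)}, which makes the FROC
#' signal reduce exactly to \eqn{\exp(-bD)} at \eqn{\beta = 1}.
#'
#' @param b_values numeric, diffusion weightings in s/mm^2; non-negative,
#'   strictly increasing, first entry 0.
#' @param delta gradient pulse duration \eqn{\delta} in ms (optional).
#' @param Delta gradient separation \eqn{\Delta} in ms (optional; must
#'   satisfy `Delta > delta/3 > 0` when given).
#' @return An object of class `bval_scheme` with elements `b`, `delta`,
#'   `Delta`, and `gd` (the derived \eqn{\gamma G_d \delta} per b-value in
#'   \eqn{\sqrt{s/mm^2 / s}} units, `NA` where timing is absent).
#' @examples
#' sch <- bval_scheme(c(0, 50, 100, 150, 200, 500, 800, 1000, 1500, 2000, 2500),
#'                    delta = 20, Delta = 40)
#' sch$b
#' @export
bval_scheme <- function(b_values, delta = NULL, Delta = NULL) {
  b_values <- as.numeric(b_values)
  if (length(b_values) < 2L)
    stop("need at least two b-values")
  if (anyNA(b_values) || any(b_values < 0))
    stop("b-values must be non-negative and finite")
  if (b_values[1L] != 0)
    stop("first b-value must be 0")
  if (any(diff(b_values) <= 0))
    stop("b-values must be strictly increasing")
  if (xor(is.null(delta), is.null(Delta)))
    stop("delta and Delta must be supplied together")
  gd <- rep(NA_real_, length(b_values))
  if (!is.null(delta)) {
    if (!(Delta > delta / 3 && delta > 0))
      stop("gradient timing requires Delta > delta/3 > 0")
    # b [s/mm^2], timings in ms -> seconds; gd = gamma*G_d*delta [rad/mm]
    gd <- sqrt(b_values / (Delta - delta / 3) * 1e3)
  }
  structure(list(b = b_values, delta = delta, Delta = Delta, gd = gd),
            class = "bval_scheme")
}

#' @export
print.bval_scheme <- function(x, ...) {
  cat("b-value scheme:", length(x$b), "b-values,",
      min(x$b), "-", max(x$b), "s/mm^2\n")
  if (!is.null(x$delta))
    cat("  gradient timing: delta =", x$delta, "ms, Delta =", x$Delta, "ms\n")
  invisible(x)
}

#' The 11-b-value acquisition used throughout
#'
#' The multi-b-value protocol of the study this package models: 0, 50, 100,
#' 150, 200, 500, 800, 1000, 1500, 2000, 2500 s/mm^2, with default gradient
#' timing delta = 20 ms, Delta = 40 ms for the FROC model (the acquisition's
#' true timing is not public; this choice preserves the b = (gGd)^2(D-d/3)
#' consistency relation).
#'
#' @param delta,Delta gradient timing in ms.
#' @return a [bval_scheme].
#' @export
default_scheme <- function(delta = 20, Delta = 40) {
  bval_scheme(c(0, 50, 100, 150, 200, 500, 800, 1000, 1500, 2000, 2500),
              delta = delta, Delta = Delta)
}

#' Read an FSL-style .bval file
#'
#' @param path path to a whitespace-separated text file of b-values.
#' @param ... passed to [bval_scheme()].
#' @return a [bval_scheme].
#' @export
read_bval <- function(path, ...) {
  if (!file.exists(path)) stop("bval file not found: ", path)
  vals <- scan(path, what = numeric(), quiet = TRUE)
  bval_scheme(vals, ...)
}

as_b <- function(scheme) {
  if (inherits(scheme, "bval_scheme")) scheme$b else as.numeric(scheme)
}
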