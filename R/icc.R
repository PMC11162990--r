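#' Two-way random-effects intraclass correlation, ICC(2,1)
#'
#' Absolute-agreement, single-measurement ICC from the two-way random
#' effects ANOVA decomposition,
#' \deqn{ICC = \frac{MS_R - MS_E}{MS_R + (k-1)MS_E + \frac{k}{n}(MS_C - MS_E)}}
#' with k = 2 raters. This is the usual reporting convention for
#' segmentation reproducibility; the agreement (not consistency) form is
#' used, so a constant offset between raters lowers the ICC.
#'
#' @param x1,x2 paired measurements of the same n >= 3 participants by the
#'   two raters.
#' @return ICC in [-1, 1], or `NA` (with a warning) when the total variance
#'   is zero.
#' @export
icc_two_way_random <- function(x1, x2) {
  if (length(x1) != length(x2)) stop("rater vectors must have equal length")
  n <- length(x1)
  if (n < 3L) stop("need at least 3 paired observations")
  if (anyNA(x1) || anyNA(x2) || any(!is.finite(c(x1, x2))))
    stop("ratings must be finite")
  k <- 2
  dat <- cbind(x1, x2)
  grand <- mean(dat)
  row_m <- rowMeans(dat); col_m <- colMeans(dat)
  SSR <- k * sum((row_m - grand)^2)
  SSC <- n * sum((col_m - grand)^2)
  SST <- sum((dat - grand)^2)
  SSE <- SST - SSR - SSC
  if (SST < .Machine$double.eps * n * k) {
    warning("zero total variance: ICC undefined")
    return(NA_real_)
  }
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
}

#' ICC-based feature filtering across two raters' feature tables
#'
#' Computes ICC(2,1) per feature between the two raters' extractions and
#' retains features with ICC at or above the threshold (the study excluded
#' features below 0.80).
#'
#' @param tableA,tableB feature tables ([build_feature_table()]) from the
#'   two raters' masks; must share id ordering and feature columns.
#' @param threshold retention threshold on the ICC.
#' @return list with `retained` (character), and `report` (data.frame
#'   `feature`, `icc`, `retained`, sorted by decreasing ICC).
#' @export
filter_by_icc <- function(tableA, tableB, threshold = 0.80) {
  fa <- feature_matrix(tableA); fb <- feature_matrix(tableB)
  if (!identical(colnames(fa), colnames(fb)))
    stop("rater tables have different feature columns")
  if (nrow(fa) != nrow(fb))
    stop("rater tables have different numbers of participants")
  icc <- vapply(seq_len(ncol(fa)),
                function(j) suppressWarnings(icc_two_way_random(fa[, j], fb[, j])),
                0)
  report <- data.frame(feature = colnames(fa), icc = icc,
                       retained = !is.na(icc) & icc >= threshold,
                       stringsAsFactors = FALSE)
  report <- report[order(-report$icc), ]
  rownames(report) <- NULL
  if (!any(report$retained))
    warning("no features meet the ICC threshold ", threshold)
  list(retained = report$feature[report$retained], report = report)
}
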