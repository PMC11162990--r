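#' ROC area under the curve (Mann-Whitney estimator)
#'
#' AUC as the proportion of positive/negative score pairs ordered
#' correctly, ties counting one half — exactly the trapezoidal ROC area.
#'
#' @param scores numeric scores or probabilities (higher = more positive).
#' @param labels binary labels (0/1).
#' @return list of class `roc_result`: `auc`, `n_pos`, `n_neg`, and the ROC
#'   `curve` (data.frame `fpr`, `tpr`).
#' @export
auc <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present")
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  r <- rank(c(pos, neg))
  a <- (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
  th <- sort(unique(scores), decreasing = TRUE)
  curve <- data.frame(
    fpr = c(0, vapply(th, function(t) mean(neg >= t), 0)),
    tpr = c(0, vapply(th, function(t) mean(pos >= t), 0)))
  structure(list(auc = a, n_pos = length(pos), n_neg = length(neg),
                 curve = curve), class = "roc_result")
}

# DeLong structural components (placements), computed via midranks
delong_placements <- function(scores, labels) {
  labels <- as.integer(labels)
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos); r_neg <- rank(neg)
  V10 <- (r_all[seq_len(m)] - r_pos) / n
  V01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = mean(V10), V10 = V10, V01 = V01, m = m, n = n)
}

#' DeLong confidence interval for a single AUC
#'
#' Normal-theory interval on the AUC scale with the DeLong
#' structural-component variance, clipped to [0, 1]. Perfectly separated
#' data yield zero variance and a degenerate interval (with a warning).
#'
#' @inheritParams auc
#' @param level confidence level.
#' @return list: `auc`, `var`, `ci` (length-2), `level`.
#' @export
delong_ci <- function(scores, labels, level = 0.95) {
  pl <- delong_placements(scores, labels)
  if (pl$m < 2L || pl$n < 2L) stop("need >= 2 observations in each class")
  v <- stats::var(pl$V10) / pl$m + stats::var(pl$V01) / pl$n
  if (v <= 0) {
    warning("degenerate DeLong variance (separated scores): zero-width CI")
    v <- 0
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  ci <- pmin(pmax(pl$auc + c(-1, 1) * z * sqrt(v), 0), 1)
  list(auc = pl$auc, var = v, ci = ci, level = level)
}

#' DeLong paired test for two correlated AUCs
#'
#' Compares AUCs of two score vectors over the same cases,
#' \eqn{z = (A_1 - A_2)/\sqrt{v_1 + v_2 - 2c}} with the paired
#' structural-component covariance.
#'
#' @param scores1,scores2 two score vectors over the same cases.
#' @param labels shared binary labels.
#' @return list: `auc1`, `auc2`, `z`, `p` (two-sided).
#' @export
delong_paired_test <- function(scores1, scores2, labels) {
  if (length(scores1) != length(scores2))
    stop("score vectors must have equal length")
  p1 <- delong_placements(scores1, labels)
  p2 <- delong_placements(scores2, labels)
  v1 <- stats::var(p1$V10) / p1$m + stats::var(p1$V01) / p1$n
  v2 <- stats::var(p2$V10) / p2$m + stats::var(p2$V01) / p2$n
  cv <- stats::cov(p1$V10, p2$V10) / p1$m + stats::cov(p1$V01, p2$V01) / p1$n
  vd <- v1 + v2 - 2 * cv
  d <- p1$auc - p2$auc
  if (vd <= .Machine$double.eps) {
    if (abs(d) < 1e-12) return(list(auc1 = p1$auc, auc2 = p2$auc, z = 0, p = 1))
    stop("zero variance of AUC difference with unequal AUCs")
  }
  z <- d / sqrt(vd)
  list(auc1 = p1$auc, auc2 = p2$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Operating point at maximal Youden index
#'
#' Sweeps all observed scores as candidate thresholds (classify positive
#' when score >= threshold) and returns the point maximizing
#' J = sensitivity + specificity - 1, ties broken toward higher
#' sensitivity.
#'
#' @inheritParams auc
#' @return list of class `operating_point`: `threshold`, `accuracy`,
#'   `sensitivity`, `specificity`, `youden`, `degenerate` flag.
#' @export
youden_operating_point <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  th <- sort(unique(scores))
  best <- NULL
  for (t in th) {
    pred <- scores >= t
    sens <- mean(pred[labels == 1L]); spec <- mean(!pred[labels == 0L])
    J <- sens + spec - 1
    if (is.null(best) || J > best$youden + 1e-12 ||
        (abs(J - best$youden) <= 1e-12 && sens > best$sensitivity)) {
      best <- list(threshold = t, accuracy = mean(pred == (labels == 1L)),
                   sensitivity = sens, specificity = spec, youden = J)
    }
  }
  best$degenerate <- best$youden <= 1e-12
  class(best) <- "operating_point"
  best
}

#' Decision-curve analysis
#'
#' Net benefit of treating according to the model,
#' \eqn{NB(p_t) = TP/N - (FP/N)\,p_t/(1-p_t)}, against treat-all and
#' treat-none strategies across a grid of threshold probabilities.
#'
#' @param probs predicted probabilities in [0, 1].
#' @param labels binary labels (0/1).
#' @param thresholds threshold-probability grid (0 and 1 excluded).
#' @return data.frame: `threshold`, `nb_model`, `nb_all`, `nb_none`.
#' @export
decision_curve <- function(probs, labels,
                           thresholds = seq(0.01, 0.99, by = 0.01)) {
  if (any(probs < 0 | probs > 1)) stop("probs must lie in [0, 1]")
  if (any(thresholds <= 0 | thresholds >= 1))
    stop("thresholds must lie strictly inside (0, 1)")
  labels <- as.integer(labels)
  N <- length(labels); prev <- mean(labels)
  nb_model <- vapply(thresholds, function(pt) {
    pred <- probs >= pt
    tp <- sum(pred & labels == 1L); fp <- sum(pred & labels == 0L)
    tp / N - fp / N * pt / (1 - pt)
  }, 0)
  nb_all <- prev - (1 - prev) * thresholds / (1 - thresholds)
  data.frame(threshold = thresholds, nb_model = nb_model,
             nb_all = nb_all, nb_none = 0)
}

#' Hosmer-Lemeshow goodness-of-fit test
#'
#' Deciles-of-risk grouping (equal-count by predicted probability; groups
#' emptied by ties are merged with a warning), statistic
#' \eqn{\sum_g (O_g - E_g)^2 / (E_g (1 - E_g/n_g))}, df = g - 2,
#' upper-tail chi-square p-value.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels (0/1).
#' @param n_groups intended number of groups.
#' @return list: `statistic`, `df`, `p`, `n_groups_used`, and the per-group
#'   table `groups`.
#' @export
hosmer_lemeshow <- function(probs, labels, n_groups = 10L) {
  labels <- as.integer(labels)
  n <- length(probs)
  if (n < 2L * n_groups) stop("need at least 2 observations per group")
  br <- unique(stats::quantile(probs, seq(0, 1, length.out = n_groups + 1L),
                               type = 7))
  if (length(br) < 3L)
    stop("predicted probabilities too concentrated for grouping")
  if (length(br) < n_groups + 1L)
    warning("tied probabilities: groups merged, df adjusted")
  g <- cut(probs, br, include.lowest = TRUE)
  tab <- data.frame(
    n = as.vector(table(g)),
    O = as.vector(tapply(labels, g, sum)),
    E = as.vector(tapply(probs, g, sum)))
  tab <- tab[tab$n > 0, ]
  gg <- nrow(tab)
  denom <- tab$E * (1 - tab$E / tab$n)
  ok <- denom > .Machine$double.eps
  stat <- sum((tab$O[ok] - tab$E[ok])^2 / denom[ok])
  df <- max(gg - 2L, 1L)
  list(statistic = stat, df = df,
       p = stats::pchisq(stat, df, lower.tail = FALSE),
       n_groups_used = gg, groups = tab)
}

#' Bootstrap mean absolute calibration error
#'
#' For each bootstrap resample, an observed-frequency calibration curve is
#' built from 10 equal-count bins of predicted probability with linear
#' interpolation between bin centers, and the mean absolute gap between
#' the curve and the identity is taken over a fixed probability grid; the
#' reported MAE averages over resamples. Deterministic given `seed`.
#'
#' @param probs predicted probabilities.
#' @param labels binary labels (0/1).
#' @param B number of bootstrap repetitions (the study used 10,000;
#'   1,000 is this package's test default).
#' @param seed integer seed.
#' @param n_bins calibration bins.
#' @param grid evaluation grid (defaults to 19 points spanning the
#'   observed probability range).
#' @return list: `mae`, `B`, `seed`.
#' @export
calibration_mae_bootstrap <- function(probs, labels, B = 1000L, seed = 1L,
                                      n_bins = 10L, grid = NULL) {
  if (B < 100L) stop("B must be at least 100")
  labels <- as.integer(labels)
  if (length(unique(probs)) < 2L) {
    # degenerate curve: a single point; flag it but still report the gap
    warning("constant predicted probabilities: calibration smoother degenerate")
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
    maes <- vapply(seq_len(B), function(b)
      abs(probs[1L] - mean(labels[sample.int(length(labels), replace = TRUE)])),
      0)
    return(list(mae = mean(maes), B = B, seed = seed))
  }
  if (is.null(grid))
    grid <- seq(stats::quantile(probs, 0.05), stats::quantile(probs, 0.95),
                length.out = 19L)
  curve_mae <- function(p, y) {
    br <- unique(stats::quantile(p, seq(0, 1, length.out = n_bins + 1L)))
    if (length(br) < 3L) return(NA_real_)
    g <- cut(p, br, include.lowest = TRUE)
    px <- as.vector(tapply(p, g, mean)); oy <- as.vector(tapply(y, g, mean))
    keep <- !is.na(px)
    obs <- stats::approx(px[keep], oy[keep], xout = grid, rule = 2)$y
    mean(abs(obs - grid))
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  maes <- vapply(seq_len(B), function(b) {
    i <- sample.int(length(probs), replace = TRUE)
    curve_mae(probs[i], labels[i])
  }, 0)
  list(mae = mean(maes, na.rm = TRUE), B = B, seed = seed)
}

#' Two-group cohort balance tests
#'
#' Continuous variables: Mann-Whitney U with the tie-corrected normal
#' approximation; categorical variables: chi-square without continuity
#' correction, switching to Fisher's exact test when any expected cell
#' count is below 5 (as in the study's Table 1 footnote).
#'
#' @param groupA,groupB vectors of the variable in the two groups
#'   (numeric for `"continuous"`; factor/character for `"categorical"`).
#' @param variable_type `"continuous"` or `"categorical"`.
#' @return list: `p`, `method`, `statistic`.
#' @export
cohort_balance_tests <- function(groupA, groupB,
                                 variable_type = c("continuous", "categorical")) {
  variable_type <- match.arg(variable_type)
  if (length(groupA) == 0L || length(groupB) == 0L)
    stop("both groups must be non-empty")
  if (variable_type == "continuous") {
    if (length(unique(c(groupA, groupB))) == 1L)
      return(list(p = 1, method = "mann-whitney", statistic = NA_real_))
    wt <- suppressWarnings(stats::wilcox.test(groupA, groupB, exact = FALSE,
                                              correct = FALSE))
    p <- if (is.nan(wt$p.value)) 1 else wt$p.value
    list(p = p, method = "mann-whitney", statistic = unname(wt$statistic))
  } else {
    tab <- table(factor(c(rep("A", length(groupA)), rep("B", length(groupB)))),
                 c(as.character(groupA), as.character(groupB)))
    exp_counts <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(exp_counts < 5)) {
      ft <- stats::fisher.test(tab)
      list(p = ft$p.value, method = "fisher", statistic = NA_real_)
    } else {
      ct <- stats::chisq.test(tab, correct = FALSE)
      list(p = ct$p.value, method = "chi-square",
           statistic = unname(ct$statistic))
    }
  }
}
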