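#' LASSO feature selection with stratified 10-fold cross-validation
#'
#' L1-penalized logistic regression over a standardized feature matrix;
#' lambda minimizes the mean cross-validated binomial deviance over a
#' 100-point log grid (the 1-SE rule is available via `rule`). Folds are
#' stratified by class and fixed by `seed`, so selection is reproducible.
#'
#' @param X numeric matrix (participants x features).
#' @param y binary labels (0/1).
#' @param n_folds folds for cross-validation.
#' @param seed integer seed for fold assignment.
#' @param rule `"min"` (default) or `"1se"`.
#' @return list of class `lasso_selection`: `selected` (character),
#'   `lambda`, `cv_lambda` / `cv_deviance` (the CV curve), `seed`.
#' @export
lasso_select <- function(X, y, n_folds = 10L, seed = 1L, rule = c("min", "1se")) {
  rule <- match.arg(rule)
  y <- as.integer(y)
  if (nrow(X) < 2L * n_folds) stop("need n >= 2 * n_folds observations")
  if (length(unique(y)) < 2L) stop("y must contain both classes")
  foldid <- stratified_folds(y, n_folds, seed)
  Xs <- scale(X)
  Xs[, attr(Xs, "scaled:scale") == 0] <- 0   # constant columns carry nothing
  cv <- suppressWarnings(
    glmnet::cv.glmnet(Xs, y, family = "binomial", foldid = foldid,
                      nlambda = 100L, lambda.min.ratio = 1e-3,
                      standardize = FALSE, type.measure = "deviance"))
  lam <- if (rule == "min") cv$lambda.min else cv$lambda.1se
  cf <- as.matrix(stats::coef(cv, s = lam))
  sel <- rownames(cf)[cf[, 1L] != 0 & rownames(cf) != "(Intercept)"]
  structure(list(selected = sel, lambda = lam, cv_lambda = cv$lambda,
                 cv_deviance = cv$cvm, seed = seed),
            class = "lasso_selection")
}

stratified_folds <- function(y, n_folds, seed) {
  foldid <- integer(length(y))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    foldid[idx] <- sample(rep_len(seq_len(n_folds), length(idx)))
  }
  foldid
}

#' Unpenalized logistic regression with Wald inference
#'
#' Maximum-likelihood logistic fit with Wald p-values
#' \eqn{2\Phi(-|\hat\beta|/SE)}. Perfect (or quasi-) separation is detected
#' from fitted probabilities pinned at 0/1 with a diverging coefficient
#' norm; the fit is then ridge-stabilized (small L2 penalty) and flagged,
#' rather than failing — small testing cohorts make separation plausible.
#'
#' @param X numeric matrix (participants x features); may have 0 columns
#'   for an intercept-only model.
#' @param y binary labels (0/1).
#' @return list of class `diagnostic_model`: `features`, `intercept`,
#'   `coefficients`, `p_values`, `separation`, `training_auc`, plus the
#'   training-data standardization-free linear predictor function via
#'   [predict_model()].
#' @export
fit_logistic <- function(X, y) {
  y <- as.integer(y)
  X <- as.matrix(X)
  dat <- data.frame(y = y, X, check.names = FALSE)
  fml <- if (ncol(X) > 0)
    stats::reformulate(sprintf("`%s`", colnames(X)), response = "y")
  else y ~ 1
  fit <- suppressWarnings(stats::glm(fml, data = dat, family = stats::binomial()))
  pr <- fit$fitted.values
  sep <- (!fit$converged) || anyNA(stats::coef(fit)) || ncol(X) >= length(y) ||
    (any(pr < 1e-8 | pr > 1 - 1e-8) &&
       sum(abs(stats::coef(fit))[-1L], na.rm = TRUE) > 50)
  if (sep && ncol(X) > 0) {
    warning("perfect/quasi separation detected: ridge-stabilized fit reported")
    co <- ridge_logistic(X, y)
  } else {
    sm <- summary(fit)$coefficients
    co <- list(est = sm[, 1L], se = sm[, 2L])
  }
  est <- co$est; se <- co$se
  names(est) <- names(se) <- c("(Intercept)", colnames(X))
  p <- 2 * stats::pnorm(-abs(est / se))
  lp <- if (ncol(X) > 0) est[1L] + X %*% est[-1L] else rep(est[1L], length(y))
  prob <- stats::plogis(drop(lp))
  tr_auc <- if (length(unique(y)) == 2L) auc(prob, y)$auc else NA_real_
  structure(list(features = colnames(X),
                 intercept = unname(est[1L]),
                 coefficients = if (ncol(X) > 0) stats::setNames(est[-1L], colnames(X)) else numeric(0),
                 p_values = if (ncol(X) > 0) stats::setNames(p[-1L], colnames(X)) else numeric(0),
                 intercept_p = unname(p[1L]),
                 separation = sep,
                 training_auc = tr_auc),
            class = "diagnostic_model")
}

ridge_logistic <- function(X, y, lambda = 1e-2) {
  if (ncol(X) == 1L) {       # glmnet needs >= 2 columns; pad with a null one
    r <- ridge_logistic(cbind(X, `..pad` = 0), y, lambda)
    return(list(est = r$est[1:2], se = r$se[1:2]))
  }
  Xs <- scale(X)
  sds <- attr(Xs, "scaled:scale"); mns <- attr(Xs, "scaled:center")
  sds[sds == 0] <- 1; Xs[, attr(Xs, "scaled:scale") == 0] <- 0
  fit <- glmnet::glmnet(Xs, y, family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE)
  bs <- as.matrix(stats::coef(fit))[, 1L]
  beta <- bs[-1L] / sds
  a0 <- bs[1L] - sum(beta * mns)
  # Wald covariance from the penalized information matrix, computed in the
  # standardized space (well-conditioned even with proportional columns,
  # e.g. energy vs total energy) and mapped back to the original scale
  lp <- bs[1L] + drop(Xs %*% bs[-1L])
  w <- stats::plogis(lp) * (1 - stats::plogis(lp))
  Xi <- cbind(1, Xs)
  H <- t(Xi) %*% (Xi * w) + diag(c(0, rep(lambda * length(y), ncol(X))))
  Vs <- solve(H)
  Tm <- diag(c(1, 1 / sds))
  Tm[1L, -1L] <- -mns / sds
  V <- Tm %*% Vs %*% t(Tm)
  list(est = stats::setNames(c(a0, beta), c("(Intercept)", colnames(X))),
       se = sqrt(pmax(diag(V), 0)))
}

#' Predicted probabilities from a diagnostic model
#'
#' @param model a `diagnostic_model`.
#' @param X feature matrix containing the model's feature columns.
#' @return numeric probabilities in (0, 1).
#' @export
predict_model <- function(model, X) {
  if (length(model$features) == 0)
    return(rep(stats::plogis(model$intercept), nrow(X)))
  miss <- setdiff(model$features, colnames(X))
  if (length(miss)) stop("missing feature column(s): ", paste(miss, collapse = ", "))
  Xm <- as.matrix(X[, model$features, drop = FALSE])
  stats::plogis(model$intercept + drop(Xm %*% model$coefficients))
}

#' Features significant in a fitted logistic model
#'
#' @param model a `diagnostic_model`.
#' @param alpha Wald p-value threshold (intercept excluded).
#' @return character vector of feature names with p < alpha.
#' @export
significant_features <- function(model, alpha = 0.05) {
  names(model$p_values)[model$p_values < alpha]
}

#' Spearman rank correlation (mid-ranks for ties)
#'
#' @param x,y equal-length numeric vectors, n >= 3.
#' @return rho in [-1, 1], or `NA` with a warning when either vector has
#'   zero rank variance.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3L) stop("need at least 3 observations")
  rx <- rank(x); ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("zero rank variance: Spearman correlation undefined")
    return(NA_real_)
  }
  stats::cor(rx, ry)
}

#' Prune correlated features, keeping the more reproducible member
#'
#' Greedy pass over feature pairs with |Spearman rho| above the threshold:
#' the pair member with the lower ICC is dropped, as in the study's
#' combined-model construction. The audit trail records every drop.
#'
#' @param features candidate feature names.
#' @param feature_mat matrix with those columns (training cohort).
#' @param icc_lookup named numeric vector of ICCs covering all features.
#' @param rho_threshold redundancy threshold on |rho|.
#' @return list of class `combined_spec`: `kept`, `audit` (data.frame
#'   `dropped`, `kept_partner`, `abs_rho`, `icc_dropped`, `icc_kept`).
#' @export
prune_redundant <- function(features, feature_mat, icc_lookup,
                            rho_threshold = 0.70) {
  miss <- setdiff(features, names(icc_lookup))
  if (length(miss)) stop("no ICC available for: ", paste(miss, collapse = ", "))
  kept <- features
  audit <- data.frame(dropped = character(), kept_partner = character(),
                      abs_rho = numeric(), icc_dropped = numeric(),
                      icc_kept = numeric(), stringsAsFactors = FALSE)
  repeat {
    if (length(kept) < 2L) break
    M <- feature_mat[, kept, drop = FALSE]
    rho <- matrix(0, length(kept), length(kept),
                  dimnames = list(kept, kept))
    for (i in seq_along(kept)) for (j in seq_along(kept)) if (i < j) {
      r <- suppressWarnings(spearman_rho(M[, i], M[, j]))
      rho[i, j] <- rho[j, i] <- if (is.na(r)) 0 else abs(r)
    }
    worst <- which(rho == max(rho), arr.ind = TRUE)[1L, ]
    if (rho[worst[1L], worst[2L]] <= rho_threshold) break
    pair <- kept[worst]
    drop <- pair[which.min(icc_lookup[pair])]
    keep <- setdiff(pair, drop)
    audit <- rbind(audit, data.frame(
      dropped = drop, kept_partner = keep,
      abs_rho = rho[worst[1L], worst[2L]],
      icc_dropped = unname(icc_lookup[drop]),
      icc_kept = unname(icc_lookup[keep]), stringsAsFactors = FALSE))
    kept <- setdiff(kept, drop)
  }
  structure(list(kept = kept, audit = audit, rho_threshold = rho_threshold),
            class = "combined_spec")
}

#' Build the combined diffusion model
#'
#' Pools the per-model significant features, prunes redundant pairs
#' (|Spearman| > threshold, lower ICC dropped), and refits an unpenalized
#' logistic model on the survivors.
#'
#' @param per_model_significant character vector (or list) of significant
#'   feature names pooled across the individual diffusion models.
#' @param feature_mat training feature matrix containing those columns.
#' @param icc_lookup named ICC vector.
#' @param y binary labels.
#' @param rho_threshold redundancy threshold.
#' @return list: `model` (a `diagnostic_model`), `spec` (a `combined_spec`).
#' @export
build_combined_model <- function(per_model_significant, feature_mat,
                                 icc_lookup, y, rho_threshold = 0.70) {
  pool <- unique(unlist(per_model_significant))
  if (length(pool) == 0L) stop("empty feature pool: no significant features")
  spec <- prune_redundant(pool, feature_mat, icc_lookup, rho_threshold)
  model <- fit_logistic(feature_mat[, spec$kept, drop = FALSE], y)
  list(model = model, spec = spec)
}
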