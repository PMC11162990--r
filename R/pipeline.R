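#' Pipeline configuration
#'
#' Collects every tunable of the diagnostic-model-building chain with the
#' study's stated settings as defaults: ICC retention threshold 0.80,
#' LASSO with stratified 10-fold cross-validation, Wald significance level
#' 0.05, Spearman redundancy threshold 0.70.
#'
#' @param icc_threshold ICC retention threshold.
#' @param alpha Wald p-value threshold for pooling features.
#' @param rho_threshold Spearman redundancy threshold.
#' @param n_folds LASSO cross-validation folds.
#' @param lasso_rule `"min"` or `"1se"` lambda rule.
#' @param seed master seed (folds, bootstrap).
#' @param mae_B bootstrap repetitions for calibration MAE (the study used
#'   10,000; scaled down by default to keep runs fast).
#' @param n_bins histogram bins for entropy/uniformity.
#' @param fit_maps if TRUE, render noisy DWI per patient and fit all six
#'   models voxel-wise before feature extraction; if FALSE (default),
#'   features are extracted from the ground-truth maps — the statistical
#'   chain is identical, and the fitting stage is validated separately.
#' @param snr Rician SNR used when `fit_maps` is TRUE.
#' @param models diffusion-model groups to build individual models for.
#' @param fit_options a [fit_options] list (used when `fit_maps` = TRUE).
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(icc_threshold = 0.80, alpha = 0.05,
                            rho_threshold = 0.70, n_folds = 10L,
                            lasso_rule = "min", seed = 1L, mae_B = 200L,
                            n_bins = 64L, fit_maps = FALSE, snr = 50,
                            models = c("CTRW", "DKI", "FROC", "IVIM",
                                       "SEM", "DWIconv"),
                            fit_options = ngdwi::fit_options()) {
  structure(as.list(environment()), class = "pipeline_config")
}

feature_group <- function(feature_names) {
  g <- sub("-.*$", "", feature_names)
  g[g == "ADC"] <- "DWIconv"
  g
}

#' Run the full diagnostic pipeline on a synthetic cohort
#'
#' Feature extraction (two raters) -> ICC filter -> per-diffusion-model
#' LASSO selection -> unpenalized logistic refit with Wald p-values ->
#' pooling of significant features -> Spearman/ICC redundancy pruning ->
#' combined logistic model -> held-out evaluation (AUC with DeLong CI,
#' Youden operating point, pairwise DeLong tests, decision curves,
#' Hosmer-Lemeshow, bootstrap calibration MAE).
#'
#' An empty significant-feature pool (expected under a null cohort) is
#' caught: the combined model degrades to intercept-only and is flagged.
#'
#' @param cohort a `synthetic_cohort` from [generate_cohort()] with both
#'   training and testing sub-cohorts.
#' @param config a [pipeline_config].
#' @return list of class `run_report`; see Details. Key entries:
#'   `feature_counts`, `icc`, `selection`, `models`, `evaluation`
#'   (per-model test metrics), `delong_matrix`, `combined_audit`.
#' @export
run_pipeline <- function(cohort, config = pipeline_config()) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  man <- cohort$manifest
  if (!any(man$cohort == "testing"))
    stop("cohort has no testing sub-cohort")

  map_sets <- lapply(cohort$patients, pipeline_maps, cohort = cohort,
                     config = config)
  masks  <- lapply(cohort$patients, `[[`, "mask")
  masksB <- lapply(cohort$patients, `[[`, "mask_b")
  excl   <- lapply(cohort$patients, `[[`, "exclusion")
  labels <- man$label

  tabA <- build_feature_table(map_sets, masks, labels, excl,
                              ids = man$id, n_bins = config$n_bins)
  tr <- man$cohort == "training"; te <- man$cohort == "testing"
  tabB_tr <- build_feature_table(map_sets[tr], masksB[tr], labels[tr],
                                 excl[tr], ids = man$id[tr],
                                 n_bins = config$n_bins)

  icc_res <- filter_by_icc(tabA[tr, ], tabB_tr, config$icc_threshold)
  icc_lookup <- stats::setNames(icc_res$report$icc, icc_res$report$feature)

  Xtr <- feature_matrix(tabA[tr, ]); ytr <- labels[tr]
  Xte <- feature_matrix(tabA[te, ]); yte <- labels[te]
  groups <- feature_group(colnames(Xtr))

  selection <- list(); models <- list(); significant <- list()
  for (m in config$models) {
    cand <- colnames(Xtr)[groups == m & colnames(Xtr) %in% icc_res$retained]
    if (length(cand) == 0L) {
      selection[[m]] <- character(0)
      models[[m]] <- fit_logistic(Xtr[, character(0), drop = FALSE], ytr)
      significant[[m]] <- character(0)
      next
    }
    sel <- lasso_select(Xtr[, cand, drop = FALSE], ytr,
                        n_folds = config$n_folds, seed = config$seed,
                        rule = config$lasso_rule)
    selection[[m]] <- sel$selected
    models[[m]] <- fit_logistic(Xtr[, sel$selected, drop = FALSE], ytr)
    significant[[m]] <- significant_features(models[[m]], config$alpha)
  }

  combined <- tryCatch(
    build_combined_model(significant, Xtr, icc_lookup, ytr,
                         config$rho_threshold),
    error = function(e) {
      list(model = fit_logistic(Xtr[, character(0), drop = FALSE], ytr),
           spec = structure(list(kept = character(0),
                                 audit = data.frame(),
                                 rho_threshold = config$rho_threshold,
                                 empty_pool = TRUE),
                            class = "combined_spec"))
    })
  models[["Combined"]] <- combined$model

  evaluation <- list(); probs_te <- list()
  for (m in names(models)) {
    pr <- predict_model(models[[m]], Xte)
    probs_te[[m]] <- pr
    evaluation[[m]] <- evaluate_model(pr, yte, config)
  }
  dl <- delong_matrix(probs_te, yte)

  structure(list(
    feature_counts = list(n_maps = 14L, n_features_per_map = 18L,
                          n_features = ncol(Xtr),
                          n_retained = length(icc_res$retained)),
    icc = icc_res$report,
    selection = selection,
    models = models,
    significant = significant,
    combined_audit = combined$spec,
    evaluation = evaluation,
    delong_matrix = dl,
    seed = config$seed,
    n_train = sum(tr), n_test = sum(te)),
    class = "run_report")
}

pipeline_maps <- function(patient, cohort, config) {
  if (!config$fit_maps) return(patient$truth)
  dwi <- patient$dwi
  if (is.null(dwi)) {
    clean <- render_signal(patient$truth, cohort$scheme, "CTRW")
    dwi <- add_rician_noise(clean, config$snr, seed = patient$seed + 3L,
                            s0_ref = 100)
  }
  fit_all_models(dwi, patient$mask, cohort$scheme,
                 options = config$fit_options,
                 voxel_size = patient$truth$voxel_size)
}

evaluate_model <- function(probs, y, config) {
  ci <- if (length(unique(probs)) > 1L) delong_ci(probs, y)
        else list(auc = 0.5, ci = c(0.5, 0.5), var = 0)
  yp <- if (length(unique(probs)) > 1L) youden_operating_point(probs, y)
        else list(threshold = NA, accuracy = max(mean(y), 1 - mean(y)),
                  sensitivity = NA, specificity = NA, youden = 0,
                  degenerate = TRUE)
  hl <- suppressWarnings(
    tryCatch(hosmer_lemeshow(probs, y),
             error = function(e) list(statistic = NA_real_, df = NA_integer_,
                                      p = NA_real_)))
  mae <- suppressWarnings(
    calibration_mae_bootstrap(probs, y, B = config$mae_B, seed = config$seed))
  dca <- decision_curve(probs, y)
  list(auc = ci$auc, auc_ci = ci$ci, operating_point = yp,
       hosmer_lemeshow = hl, calibration_mae = mae$mae, dca = dca)
}

delong_matrix <- function(probs_list, y) {
  nm <- names(probs_list)
  P <- matrix(NA_real_, length(nm), length(nm), dimnames = list(nm, nm))
  for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j) {
    p <- tryCatch(
      delong_paired_test(probs_list[[i]], probs_list[[j]], y)$p,
      error = function(e) NA_real_)
    P[i, j] <- P[j, i] <- p
  }
  P
}

#' @export
print.run_report <- function(x, ...) {
  fc <- x$feature_counts
  cat("diagnostic pipeline report\n")
  cat(sprintf("  features: %d maps x %d = %d (%d retained at ICC filter)\n",
              fc$n_maps, fc$n_features_per_map, fc$n_features, fc$n_retained))
  cat(sprintf("  cohorts: %d training / %d testing\n", x$n_train, x$n_test))
  for (m in names(x$evaluation)) {
    ev <- x$evaluation[[m]]
    cat(sprintf("  %-8s test AUC %.3f (%.3f-%.3f), %d features\n",
                m, ev$auc, ev$auc_ci[1L], ev$auc_ci[2L],
                length(x$models[[m]]$features)))
  }
  invisible(x)
}
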