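#!/usr/bin/env Rscript

# Stage 5 — held-out evaluation.
#
# For every task and model: AUC with DeLong 95% CI, operating point at
# maximal Youden index, Hosmer-Lemeshow calibration, bootstrap calibration
# MAE, decision curves, and the pairwise DeLong comparison matrix (the
# analogue of the study's model-comparison table).

suppressMessages(library(ngdwi))
dir.create("results", showWarnings = FALSE)

seed <- 20240609L
for (task in c("invasion", "grade", "null")) {
  pred <- read.csv(sprintf("results/predictions_%s.csv", task),
                   check.names = FALSE)
  y <- pred$label
  model_cols <- setdiff(colnames(pred), c("id", "label"))
  metrics <- list(); dca_rows <- list()
  for (m in model_cols) {
    pr <- pred[[m]]
    if (length(unique(pr)) < 2L) {
      metrics[[m]] <- list(auc = 0.5, note = "constant predictions")
      next
    }
    ci <- delong_ci(pr, y)
    op <- youden_operating_point(pr, y)
    hl <- suppressWarnings(tryCatch(hosmer_lemeshow(pr, y),
                                    error = function(e) NULL))
    mae <- suppressWarnings(
      calibration_mae_bootstrap(pr, y, B = 1000, seed = seed))
    metrics[[m]] <- list(
      auc = ci$auc, auc_ci = ci$ci,
      accuracy = op$accuracy, sensitivity = op$sensitivity,
      specificity = op$specificity, youden_threshold = op$threshold,
      hl_statistic = if (is.null(hl)) NA else hl$statistic,
      hl_p = if (is.null(hl)) NA else hl$p,
      calibration_mae = mae$mae)
    dc <- decision_curve(pr, y)
    dc$model <- m
    dca_rows[[m]] <- dc
  }
  jsonlite::write_json(metrics, sprintf("results/metrics_%s.json", task),
                       auto_unbox = TRUE, digits = NA)
  write.csv(do.call(rbind, dca_rows),
            sprintf("results/decision_curves_%s.csv", task), row.names = FALSE)

  dl <- matrix(NA_real_, length(model_cols), length(model_cols),
               dimnames = list(model_cols, model_cols))
  for (i in seq_along(model_cols)) for (j in seq_along(model_cols))
    if (i < j) {
      p <- tryCatch(delong_paired_test(pred[[model_cols[i]]],
                                       pred[[model_cols[j]]], y)$p,
                    error = function(e) NA_real_)
      dl[i, j] <- dl[j, i] <- p
    }
  write.csv(round(dl, 4), sprintf("results/delong_matrix_%s.csv", task))

  aucs <- vapply(metrics, function(m) m$auc, 0)
  message(sprintf("%-8s held-out AUCs: %s", task,
                  paste(sprintf("%s %.3f", names(aucs), aucs), collapse = ", ")))
}
message("wrote results/metrics_*.json, decision_curves_*.csv, delong_matrix_*.csv")
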