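#!/usr/bin/env Rscript

# Stage 4 — diagnostic model building.
#
# For each task: per-diffusion-model LASSO (stratified 10-fold CV, lambda at
# minimum CV deviance) on the ICC-retained features of the training cohort,
# unpenalized logistic refit with Wald p-values, pooling of the p < 0.05
# features, Spearman/ICC redundancy pruning (|rho| > 0.70 drops the
# lower-ICC member), and the combined logistic model. Writes model cards
# (feature, coefficient, p — the analogue of the study's per-model tables)
# and the held-out predicted probabilities for stage 5.

suppressMessages(library(ngdwi))
dir.create("results", showWarnings = FALSE)

seed <- 20240609L
for (task in c("invasion", "grade", "null")) {
  tab <- read_feature_csv(sprintf("scratch/features_%s_raterA.csv", task))
  icc_rep <- read.csv(sprintf("results/icc_%s.csv", task), check.names = FALSE)
  icc_lookup <- setNames(icc_rep$icc, icc_rep$feature)
  retained <- icc_rep$feature[icc_rep$retained]

  tr <- tab$cohort == "training"; te <- tab$cohort == "testing"
  X <- feature_matrix(tab); y <- tab$label
  groups <- ngdwi:::feature_group(colnames(X))

  cards <- list(); sig <- list(); preds <- list()
  for (m in c("CTRW", "DKI", "FROC", "IVIM", "SEM", "DWIconv")) {
    cand <- colnames(X)[groups == m & colnames(X) %in% retained]
    sel <- lasso_select(X[tr, cand, drop = FALSE], y[tr], seed = seed)
    fit <- suppressWarnings(
      fit_logistic(X[tr, sel$selected, drop = FALSE], y[tr]))
    sig[[m]] <- significant_features(fit)
    cards[[m]] <- list(
      lambda = sel$lambda, separation = fit$separation,
      training_auc = fit$training_auc,
      intercept = fit$intercept,
      features = data.frame(feature = fit$features,
                            coef = unname(fit$coefficients),
                            p = unname(fit$p_values)))
    preds[[m]] <- predict_model(fit, X[te, , drop = FALSE])
  }
  comb <- tryCatch(
    build_combined_model(sig, X[tr, , drop = FALSE], icc_lookup, y[tr]),
    error = function(e) NULL)
  if (is.null(comb)) {
    message(task, ": empty significant pool; combined model is intercept-only")
    fitc <- fit_logistic(X[tr, character(0), drop = FALSE], y[tr])
    audit <- data.frame()
  } else {
    fitc <- comb$model
    audit <- comb$spec$audit
  }
  cards[["Combined"]] <- list(
    training_auc = fitc$training_auc, intercept = fitc$intercept,
    features = data.frame(feature = fitc$features,
                          coef = unname(fitc$coefficients),
                          p = unname(fitc$p_values)),
    pruning_audit = audit)
  preds[["Combined"]] <- predict_model(fitc, X[te, , drop = FALSE])

  jsonlite::write_json(cards, sprintf("results/model_cards_%s.json", task),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  pred_df <- data.frame(id = tab$id[te], label = y[te],
                        do.call(cbind, preds), check.names = FALSE)
  write.csv(pred_df, sprintf("results/predictions_%s.csv", task),
            row.names = FALSE)
  message(sprintf("%-8s combined model: %d features (%s)", task,
                  length(fitc$features),
                  paste(fitc$features, collapse = ", ")))
}
message("wrote results/model_cards_*.json and results/predictions_*.csv")
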