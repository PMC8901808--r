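#!/usr/bin/env Rscript
# Stage 4 — feature selection, logistic model and evaluation.
#
# Reduces each arm's feature table at the stage-3 parameters, runs the
# 25-seed LASSO -> logistic -> Youden protocol (scaled from the study's 100
# seeds), freezes the model from the seed with the highest training
# accuracy, and reports AUC / sensitivity / specificity / PPV / NPV /
# accuracy / YI on the training, validation and resolution-shifted test
# splits for both arms side by side.

suppressMessages(library(slnradiomics))

SEED <- 1L
params_by_arm <- jsonlite::read_json("results/reduction_params.json")

metrics <- c("auc", "sensitivity", "specificity", "ppv", "npv",
             "accuracy", "youden")
summary_rows <- list()

for (arm in c("cr", "dlb")) {
  tables <- lapply(c(train = "train", validation = "validation", test = "test"),
                   function(sp) read_feature_table(
                     sprintf("scratch/features/%s_%s.csv", arm, sp)))
  labels <- lapply(tables, `[[`, "labels")
  xs <- lapply(tables, `[[`, "x")
  p <- params_by_arm[[arm]]
  pca <- if (is.null(p$pca_components)) NA else p$pca_components
  params <- reduction_params(p$p_threshold, p$rho_threshold, pca)
  red <- suppressWarnings(reduce_features(xs, labels, params, seed = SEED))
  fit <- suppressWarnings(run_seed_protocol(red, labels,
                                            model_config(n_seeds = 25L)))
  cat(sprintf("\n%s arm: %d features in, %d selected (winning seed %d):\n",
              toupper(arm), ncol(red$train), length(fit$selected),
              fit$winning_seed))
  cat(" ", paste(fit$selected, collapse = "\n  "), "\n")
  for (sp in c("train_original", "validation", "test")) {
    r <- fit$reports[[sp]]
    cat(sprintf("  %-14s ", sp))
    cat(sprintf("%s=%.2f ", metrics, vapply(metrics, function(m) r[[m]],
                                            numeric(1))), "\n")
    summary_rows[[length(summary_rows) + 1L]] <-
      data.frame(arm = toupper(arm), split = sp,
                 t(vapply(metrics, function(m) r[[m]], numeric(1))))
  }
  jsonlite::write_json(
    list(params = unclass(params), selected = fit$selected,
         threshold = fit$threshold, winning_seed = fit$winning_seed,
         reports = lapply(fit$reports, function(r) r[metrics])),
    sprintf("results/model_report_%s.json", arm),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

perf <- do.call(rbind, summary_rows)
write.csv(perf, "results/performance_summary.csv", row.names = FALSE)
cat("\nwrote results/model_report_{cr,dlb}.json and results/performance_summary.csv\n")
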