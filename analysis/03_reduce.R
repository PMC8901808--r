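#!/usr/bin/env Rscript
# Stage 3 — reduction hyperparameter search.
#
# For each arm, searches the Mann-Whitney p / Spearman rho grid (no-PCA
# sub-grid; 5 protocol seeds per cell, scaled from the study's 100) for the
# cell with the highest mean validation accuracy, exactly as the protocol
# prescribes. Writes the per-cell summary and the chosen parameters.

suppressMessages(library(slnradiomics))

SEED <- 1L
dir.create("results", showWarnings = FALSE)

grid <- expand.grid(p_threshold = c(0.001, 0.005, 0.01, 0.05),
                    rho_threshold = c(0.75, 0.85, 0.95),
                    pca_components = NA)

chosen <- list()
for (arm in c("cr", "dlb")) {
  tables <- lapply(c(train = "train", validation = "validation", test = "test"),
                   function(sp) read_feature_table(
                     sprintf("scratch/features/%s_%s.csv", arm, sp)))
  labels <- lapply(tables, `[[`, "labels")
  xs <- lapply(tables, `[[`, "x")
  gs <- suppressWarnings(
    select_reduction_params(grid, xs, labels, n_seeds = 5L,
                            model_config = model_config(n_seeds = 5L)))
  cat(sprintf("%s arm: best cell p=%g rho=%g pca=none (mean val acc %.3f)\n",
              toupper(arm), gs$params$p_threshold, gs$params$rho_threshold,
              max(gs$summary$mean_validation_accuracy, na.rm = TRUE)))
  write.csv(gs$summary, sprintf("results/reduction_grid_%s.csv", arm),
            row.names = FALSE)
  chosen[[arm]] <- unclass(gs$params)
}
jsonlite::write_json(chosen, "results/reduction_params.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
cat("wrote results/reduction_grid_{cr,dlb}.csv and results/reduction_params.json\n")
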