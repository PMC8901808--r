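#!/usr/bin/env Rscript
# Stage 2 — kinetic maps and feature extraction, both arms.
#
# Regenerates the stage-1 cohort deterministically, computes the wash-in /
# wash-out / SER maps, builds the intratumoral + 0-4 mm peritumoral ROIs and
# extracts (a) the 146-feature conventional-radiomics catalog and (b) the
# 2x1000 frozen-backbone DLB features, per split. Feature tables go to
# scratch/features/ as CSV for the reduction and modeling stages.

suppressMessages(library(slnradiomics))

SEED <- 1L
dir.create("scratch/features", recursive = TRUE, showWarnings = FALSE)

cfg <- phantom_config(seed = SEED)
cohort <- generate_cohort(cfg)
splits <- split_cohort(cohort, cfg,
                       train_fraction = cfg$n_train / (cfg$n_train + cfg$n_val))
backbone <- backbone_config(seed = SEED)

for (arm in c("CR", "DLB")) {
  for (sp in names(splits)) {
    t0 <- Sys.time()
    tb <- extract_feature_table(splits[[sp]], arm = arm,
                                analysis = "intra_peri", backbone = backbone)
    path <- sprintf("scratch/features/%s_%s.csv", tolower(arm), sp)
    write_feature_table(tb, path)
    cat(sprintf("%s %-10s %3d subjects x %4d features  (%.1f s) -> %s\n",
                arm, sp, nrow(tb$x), ncol(tb$x),
                as.numeric(difftime(Sys.time(), t0, units = "secs")), path))
  }
}
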