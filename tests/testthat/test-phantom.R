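# Synthetic cohort generator: determinism, geometry, enhancement semantics,
# planted signal and the cohort split.

test_that("cohorts are byte-identical under a fixed seed", {
  cfg <- quick_config(seed = 1)
  c1 <- generate_cohort(cfg)
  c2 <- generate_cohort(cfg)
  expect_identical(c1, c2)
  s1 <- split_cohort(c1, cfg)
  s2 <- split_cohort(c2, cfg)
  expect_identical(s1, s2)
  # different seed changes the cohort
  c3 <- generate_cohort(quick_config(seed = 2))
  expect_false(identical(c1$studies[[1]]$phases[[1]], c3$studies[[1]]$phases[[1]]))
})

test_that("zero-enhancement latents leave phases at baseline and wash-in near 0", {
  st <- make_tumor_phantom(list(baseline = 100, washin = 0, washout = 0,
                                heterogeneity = 0.1, radii_mm = c(6, 6, 4)),
                           grid = c(36, 36, 8), spacing = c(0.7, 0.7, 2),
                           seed = 2)
  km <- compute_kinetic_maps(st)
  m <- st$intratumoral_mask
  expect_lt(abs(mean(km$wash_in[m], na.rm = TRUE)), 2)  # centred at 0 (% units)
  for (p in 2:5)
    expect_lt(abs(mean(st$phases[[p]] - st$phases[[1]])), 2)
})

test_that("plateau uptake of amplitude a gives S1 ~= S0 (1 + a)", {
  a <- 1.2
  st <- make_tumor_phantom(list(baseline = 100, washin = a, washout = 0,
                                heterogeneity = 0.05, radii_mm = c(7, 7, 4.5)),
                           grid = c(40, 40, 10), spacing = c(0.7, 0.7, 2),
                           seed = 3)
  m <- st$intratumoral_mask
  ratio <- mean(st$phases[[2]][m]) / mean(st$phases[[1]][m])
  expect_lt(abs(ratio - (1 + a)) / (1 + a), 0.05)
})

test_that("voxel counts scale with the in-plane resolution for a fixed physical tumor", {
  lat <- list(baseline = 100, washin = 1, washout = 0.2, heterogeneity = 0.1,
              radii_mm = c(6, 6, 4))
  st07 <- make_tumor_phantom(lat, c(48, 48, 10), c(0.7, 0.7, 2), seed = 4)
  st078 <- make_tumor_phantom(lat, c(48, 48, 10), c(0.78, 0.78, 2), seed = 4)
  ratio <- sum(st078$intratumoral_mask) / sum(st07$intratumoral_mask)
  expect_lt(abs(ratio - (0.7 / 0.78)^2), 0.05)
  # a grid too small for 64 voxels errors
  expect_error(make_tumor_phantom(list(radii_mm = c(0.5, 0.5, 0.5)),
                                  c(10, 10, 3), c(0.7, 0.7, 2), seed = 1),
               "64")
})

test_that("large planted wash-out effect separates classes at AUC > 0.9", {
  cfg <- phantom_config(n_train = 140, n_val = 40, n_test = 20,
                        positive_fraction = 0.5,
                        grid_shape = c(28L, 28L, 8L),
                        effect_sizes = list(washout_mean = 2.0, washin_mean = 0,
                                            texture_heterogeneity = 0),
                        seed = 11)
  coh <- generate_cohort(cfg)
  wo_mean <- vapply(coh$studies, function(st) {
    km <- compute_kinetic_maps(st)
    mean(km$wash_out[st$intratumoral_mask], na.rm = TRUE)
  }, numeric(1))
  lab <- vapply(coh$studies, `[[`, logical(1), "label")
  expect_gt(oracle_auc_pairs(wo_mean, lab), 0.9)
  # and the manifest declares the planted mechanism
  expect_true("kinetic:washout_mean" %in% coh$manifest$planted_mechanisms)
})

test_that("null configuration plants no signal", {
  cfg <- phantom_config(n_train = 30, n_val = 10, n_test = 5,
                        grid_shape = c(28L, 28L, 8L),
                        effect_sizes = list(washout_mean = 0, washin_mean = 0,
                                            texture_heterogeneity = 0),
                        clinical_effects = list(lymphovascular_invasion = 0,
                                                tumor_grade = 0),
                        seed = 12)
  coh <- generate_cohort(cfg)
  expect_length(coh$manifest$planted_mechanisms, 0L)
  # permutation check on the washout latent: observed |diff| is not extreme
  lat <- coh$manifest$latents
  obs <- abs(mean(lat$washout[lat$label]) - mean(lat$washout[!lat$label]))
  perm <- withr::with_seed(1, vapply(1:500, function(i) {
    pl <- sample(lat$label)
    abs(mean(lat$washout[pl]) - mean(lat$washout[!pl]))
  }, numeric(1)))
  expect_gt(mean(perm >= obs), 0.01)
})

test_that("splits honour sizes, resolutions, disjointness and the 109/54 example", {
  cfg <- quick_config(n_train = 10, n_val = 5, n_test = 4, seed = 5)
  coh <- generate_cohort(cfg)
  sp <- split_cohort(coh, cfg, train_fraction = 10 / 15)
  expect_length(sp$train, 10L)
  expect_length(sp$validation, 5L)
  expect_length(sp$test, 4L)
  ids <- lapply(sp, function(ss) vapply(ss, `[[`, character(1), "subject_id"))
  expect_equal(length(unique(unlist(ids))), 19L)            # disjoint, exhaustive
  expect_true(all(vapply(sp$test, function(s) s$spacing[1], numeric(1)) == 0.78))
  expect_true(all(vapply(sp$train, function(s) s$spacing[1], numeric(1)) == 0.7))
  # 163 main-resolution subjects at 67/33 -> 109/54
  expect_equal(round(163 * 2 / 3), 109)
  expect_identical(split_cohort(coh, cfg), split_cohort(coh, cfg))
  # all subjects at the main resolution -> no test split
  cfg_same <- quick_config(seed = 6)
  cfg_same$inplane_res_test <- cfg_same$inplane_res_main
  coh_same <- generate_cohort(cfg_same)
  expect_error(split_cohort(coh_same, cfg_same), "empty-split")
})

test_that("clinical encoding has exactly 11 numeric entries and planted association", {
  v <- encode_clinical(quick_clinical())
  expect_length(v, 11L)
  expect_true(all(is.finite(v)))
  expect_equal(v[["lymphovascular_invasion"]], 1)
  expect_equal(sum(v[grep("molecular_subtype", names(v))]), 1)
  expect_equal(sum(v[grep("pathological_type", names(v))]), 1)
  # association strength: LVI much likelier among positives at default effects
  cfg <- quick_config(n_train = 120, n_val = 40, n_test = 10, seed = 13)
  coh <- generate_cohort(cfg)
  lvi <- vapply(coh$studies, function(s) s$clinical$lymphovascular_invasion,
                logical(1))
  lab <- vapply(coh$studies, `[[`, logical(1), "label")
  expect_gt(mean(lvi[lab]), mean(lvi[!lab]) + 0.15)
})
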