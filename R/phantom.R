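#' Phantom cohort configuration
#'
#' Defines the synthetic DCE-MRI cohort that stands in for patient data: a
#' main cohort (train + validation) at one in-plane resolution and an
#' independent test cohort at a slightly different in-plane resolution, with
#' class signal planted through contrast kinetics (positives wash out faster
#' and enhance more heterogeneously) and through clinical covariates
#' (lymphovascular invasion and tumor grade associated with the label).
#'
#' Effect sizes are standardized mean differences on the latent kinetic
#' parameters; clinical effects are log odds-ratios for covariate/label
#' association.
#'
#' @param n_train,n_val number of subjects at the main resolution destined for
#'   the training and validation splits.
#' @param n_test number of subjects at the test resolution.
#' @param positive_fraction marginal probability of a positive sentinel node.
#' @param inplane_res_main,inplane_res_test in-plane voxel pitch, mm.
#' @param slice_thickness slice pitch, mm.
#' @param grid_shape integer voxel grid (x, y, z).
#' @param effect_sizes list with `washout_mean`, `washin_mean`,
#'   `texture_heterogeneity`: standardized latent shifts for positives.
#' @param clinical_effects list with `lymphovascular_invasion`, `tumor_grade`:
#'   log odds-ratio style shifts for positives.
#' @param noise_sd_frac phase-noise standard deviation as a fraction of the
#'   baseline signal.
#' @param seed integer master seed; the whole cohort is a pure function of the
#'   configuration.
#' @return object of class `phantom_config`.
#' @export
phantom_config <- function(n_train = 109L, n_val = 54L, n_test = 35L,
                           positive_fraction = 0.34,
                           inplane_res_main = 0.7, inplane_res_test = 0.78,
                           slice_thickness = 2.0,
                           grid_shape = c(48L, 48L, 12L),
                           effect_sizes = list(washout_mean = 1.5,
                                               washin_mean = 0.5,
                                               texture_heterogeneity = 1.0),
                           clinical_effects = list(lymphovascular_invasion = 2.0,
                                                   tumor_grade = 1.0),
                           noise_sd_frac = 0.05,
                           seed = 1L) {
  stopifnot(n_train > 0, n_val > 0, n_test > 0,
            positive_fraction > 0, positive_fraction < 1,
            inplane_res_main > 0, inplane_res_test > 0, slice_thickness > 0,
            length(grid_shape) == 3L, all(grid_shape >= 1))
  defaults_es <- list(washout_mean = 1.5, washin_mean = 0.5,
                      texture_heterogeneity = 1.0)
  defaults_ce <- list(lymphovascular_invasion = 2.0, tumor_grade = 1.0)
  es <- utils::modifyList(defaults_es, effect_sizes)
  ce <- utils::modifyList(defaults_ce, clinical_effects)
  structure(list(
    n_train = as.integer(n_train), n_val = as.integer(n_val),
    n_test = as.integer(n_test),
    positive_fraction = positive_fraction,
    inplane_res_main = inplane_res_main,
    inplane_res_test = inplane_res_test,
    slice_thickness = slice_thickness,
    grid_shape = as.integer(grid_shape),
    effect_sizes = es, clinical_effects = ce,
    noise_sd_frac = noise_sd_frac,
    seed = as.integer(seed)
  ), class = "phantom_config")
}

#' Construct a single-subject DCE phantom study
#'
#' Builds a five-phase dynamic series around an ellipsoidal tumor. The
#' voxelwise enhancement curve is piecewise linear: baseline S0, rapid rise to
#' the first post-contrast phase S1 = S0 * (1 + a * f), then linear washout to
#' S4 = S1 * (1 - w * f_w) (background tissue enhances mildly and plateaus).
#' `f` is a smoothed unit-mean random field whose spatial dispersion is the
#' subject's texture-heterogeneity latent, so second-order texture is
#' non-degenerate.
#'
#' @param latents list with `baseline`, `washin` (uptake amplitude a),
#'   `washout` (fractional signal loss w in [0, 1)), `heterogeneity`
#'   (dispersion of the enhancement field), optional radii `radii_mm`.
#' @param grid integer voxel grid (x, y, z).
#' @param spacing mm voxel pitch (x, y, z).
#' @param seed integer seed.
#' @param noise_sd_frac phase-noise SD as fraction of baseline.
#' @param label logical SLN status carried into the study.
#' @param clinical optional clinical record list.
#' @param subject_id identifier string.
#' @return object of class `dce_study` with fields `phases` (list of 5 3D
#'   arrays), `spacing`, `intratumoral_mask`, `label`, `clinical`,
#'   `subject_id`.
#' @export
make_tumor_phantom <- function(latents, grid, spacing, seed,
                               noise_sd_frac = 0.05, label = FALSE,
                               clinical = NULL, subject_id = "S000") {
  grid <- as.integer(grid)
  stopifnot(length(grid) == 3L, length(spacing) == 3L)
  radii <- latents$radii_mm %||% c(6.5, 6.5, 4.0)
  mask <- ellipsoid_mask(grid, spacing, radii)
  if (sum(mask) < 64L)
    stop_named("grid-too-small",
               "grid %s at spacing %s cannot hold a >=64-voxel tumor (got %d)",
               paste(grid, collapse = "x"),
               paste(signif(spacing, 3), collapse = "x"), sum(mask))

  with_seed(seed, {
    b <- latents$baseline %||% 100
    a <- latents$washin %||% 1.5
    w <- latents$washout %||% 0.2
    h <- latents$heterogeneity %||% 0.15

    # smoothed zero-mean unit-SD field, scaled by heterogeneity
    g <- array(rnorm(prod(grid)), dim = grid)
    g <- smooth_gaussian3d(g, sigma_vox = c(1.5, 1.5, 0.75))
    g <- (g - mean(g)) / max(sd(g), 1e-12)
    f <- 1 + h * g                       # unit-mean enhancement field
    fw <- 1 + h * g                      # washout shares the texture field

    amp <- ifelse(mask, a * f, 0.15 * a) # mild uniform background enhancement
    wo <- ifelse(mask, pmin(pmax(w * fw, 0), 0.95), 0)

    s0 <- b * (1 + noise_sd_frac * array(rnorm(prod(grid)), dim = grid))
    s0 <- pmax(s0, b * 0.2)
    s1_clean <- s0 * (1 + amp)
    s4_clean <- s1_clean * (1 - wo)
    phases <- vector("list", 5L)
    phases[[1]] <- s0
    for (p in 2:5) {
      t <- (p - 2) / 3                   # 0 at S1, 1 at S4
      clean <- s1_clean + t * (s4_clean - s1_clean)
      phases[[p]] <- clean + b * noise_sd_frac * array(rnorm(prod(grid)), dim = grid)
    }
    new_dce_study(phases, spacing, mask, label, clinical, subject_id)
  })
}

ellipsoid_mask <- function(grid, spacing, radii_mm) {
  cx <- (grid + 1) / 2
  x <- ((seq_len(grid[1]) - cx[1]) * spacing[1] / radii_mm[1])^2
  y <- ((seq_len(grid[2]) - cx[2]) * spacing[2] / radii_mm[2])^2
  z <- ((seq_len(grid[3]) - cx[3]) * spacing[3] / radii_mm[3])^2
  r2 <- outer(outer(x, y, `+`), z, `+`)
  r2 <= 1
}

new_dce_study <- function(phases, spacing, mask, label, clinical, subject_id) {
  stopifnot(length(phases) == 5L)
  dm <- dim(phases[[1]])
  for (p in phases) {
    if (!identical(dim(p), dm)) stop_named("phase-shape", "phase shapes differ")
  }
  if (!identical(dim(mask), dm)) stop_named("mask-shape", "mask grid mismatch")
  if (sum(mask) < 1L) stop_named("empty-mask", "intratumoral mask is empty")
  structure(list(phases = phases, spacing = as.numeric(spacing),
                 intratumoral_mask = mask, label = isTRUE(label),
                 clinical = clinical, subject_id = subject_id),
            class = "dce_study")
}

#' Generate a phantom cohort
#'
#' Draws per-subject labels, latent kinetic parameters and clinical records
#' under the configured planted effects, then renders each subject's
#' five-phase study. Subjects `1..(n_train+n_val)` are rendered at the main
#' in-plane resolution, the remaining `n_test` at the test resolution; tumor
#' size is drawn in millimetres so the test cohort's masks carry fewer voxels
#' for the same physical tumor.
#'
#' @param config a [phantom_config()].
#' @return list with `studies` (list of `dce_study`) and `manifest` (a
#'   `ground_truth_manifest`: per-subject latent table, the planted-mechanism
#'   list and the cohort seed).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "phantom_config"))
  n_main <- config$n_train + config$n_val
  n <- n_main + config$n_test
  es <- config$effect_sizes
  ce <- config$clinical_effects

  with_seed(config$seed, {
    label <- runif(n) < config$positive_fraction
    pos <- as.numeric(label)

    # latent kinetic parameters (standardized shifts for positives)
    washout <- 0.20 + 0.06 * (rnorm(n) + es$washout_mean * pos)
    washout <- pmin(pmax(washout, 0.01), 0.6)
    washin <- exp(log(1.5) + 0.25 * (rnorm(n) + es$washin_mean * pos))
    heterogeneity <- abs(0.15 + 0.05 * (rnorm(n) + es$texture_heterogeneity * pos))
    baseline <- rnorm(n, 100, 10)
    baseline <- pmax(baseline, 60)

    radii <- cbind(runif(n, 5, 8), runif(n, 5, 8), runif(n, 3, 5))

    clinical <- lapply(seq_len(n), function(i)
      draw_clinical_record(pos[i], ce))

    sub_seeds <- sample.int(.Machine$integer.max - 1L, n)

    studies <- vector("list", n)
    for (i in seq_len(n)) {
      res <- if (i <= n_main) config$inplane_res_main else config$inplane_res_test
      spacing <- c(res, res, config$slice_thickness)
      studies[[i]] <- make_tumor_phantom(
        latents = list(baseline = baseline[i], washin = washin[i],
                       washout = washout[i], heterogeneity = heterogeneity[i],
                       radii_mm = radii[i, ]),
        grid = config$grid_shape, spacing = spacing, seed = sub_seeds[i],
        noise_sd_frac = config$noise_sd_frac, label = label[i],
        clinical = clinical[[i]],
        subject_id = sprintf("S%03d", i))
    }

    manifest <- structure(list(
      latents = data.frame(
        subject_id = sprintf("S%03d", seq_len(n)),
        label = label, baseline = baseline, washin = washin,
        washout = washout, heterogeneity = heterogeneity,
        resolution = c(rep(config$inplane_res_main, n_main),
                       rep(config$inplane_res_test, config$n_test)),
        stringsAsFactors = FALSE),
      planted_mechanisms = c(
        if (es$washout_mean != 0) "kinetic:washout_mean",
        if (es$washin_mean != 0) "kinetic:washin_mean",
        if (es$texture_heterogeneity != 0) "kinetic:texture_heterogeneity",
        if (ce$lymphovascular_invasion != 0) "clinical:lymphovascular_invasion",
        if (ce$tumor_grade != 0) "clinical:tumor_grade"),
      clinical_effects = ce,
      seed = config$seed), class = "ground_truth_manifest")

    list(studies = studies, manifest = manifest)
  })
}

draw_clinical_record <- function(pos, ce) {
  lvi_p <- plogis(qlogis(0.15) + ce$lymphovascular_invasion * pos)
  grade_latent <- rnorm(1) + ce$tumor_grade * pos
  grade <- cut(grade_latent, c(-Inf, -0.4, 0.9, Inf), labels = FALSE)
  list(
    upper_inner_quadrant = runif(1) < 0.12,
    multifocality = runif(1) < 0.20,
    age = round(rnorm(1, 55, 10), 1),
    pathological_type = sample(c("ductal", "lobular"), 1, prob = c(0.85, 0.15)),
    tumor_grade = grade,
    molecular_subtype = sample(c("luminal_a", "luminal_b", "her2", "triple_negative"),
                               1, prob = c(0.5, 0.25, 0.13, 0.12)),
    lymphovascular_invasion = runif(1) < lvi_p
  )
}

#' Encode a clinical record as the 11-number covariate vector
#'
#' Five fields kept as-is (upper inner quadrant, multifocality, age, tumor
#' grade as ordinal, lymphovascular invasion) plus one-hot pathological type
#' (2 levels) and molecular subtype (4 levels).
#'
#' @param rec clinical record list.
#' @return named numeric vector of length 11.
#' @export
encode_clinical <- function(rec) {
  stopifnot(!is.null(rec))
  pt <- c(ductal = 0, lobular = 0)
  pt[rec$pathological_type] <- 1
  ms <- c(luminal_a = 0, luminal_b = 0, her2 = 0, triple_negative = 0)
  ms[rec$molecular_subtype] <- 1
  v <- c(upper_inner_quadrant = as.numeric(rec$upper_inner_quadrant),
         multifocality = as.numeric(rec$multifocality),
         age = as.numeric(rec$age),
         tumor_grade = as.numeric(rec$tumor_grade),
         lymphovascular_invasion = as.numeric(rec$lymphovascular_invasion),
         pathological_type_ductal = pt[["ductal"]],
         pathological_type_lobular = pt[["lobular"]],
         molecular_subtype_luminal_a = ms[["luminal_a"]],
         molecular_subtype_luminal_b = ms[["luminal_b"]],
         molecular_subtype_her2 = ms[["her2"]],
         molecular_subtype_triple_negative = ms[["triple_negative"]])
  stopifnot(length(v) == 11L)
  v
}

#' Split a cohort into train / validation / test
#'
#' The test split is exactly the subjects rendered at the test in-plane
#' resolution; the remaining (main-resolution) subjects are partitioned at
#' random into train and validation at the given ratio, deterministically
#' from `seed`.
#'
#' @param cohort result of [generate_cohort()].
#' @param config the [phantom_config()] used to build it.
#' @param train_fraction fraction of main-resolution subjects assigned to
#'   training (rounded to the nearest integer count).
#' @param seed split seed; defaults to the cohort seed.
#' @return list of `dce_study` lists: `train`, `validation`, `test`.
#' @export
split_cohort <- function(cohort, config, train_fraction = 2 / 3, seed = NULL) {
  studies <- cohort$studies
  res <- vapply(studies, function(s) s$spacing[1], numeric(1))
  is_test <- abs(res - config$inplane_res_test) < 1e-9 &
    abs(config$inplane_res_test - config$inplane_res_main) > 1e-9
  main_idx <- which(!is_test)
  test_idx <- which(is_test)
  if (length(test_idx) == 0L)
    stop_named("empty-split", "no subjects at the test resolution")
  if (length(main_idx) < 2L)
    stop_named("empty-split", "too few main-resolution subjects to split")
  n_tr <- round(length(main_idx) * train_fraction)
  n_tr <- min(max(n_tr, 1L), length(main_idx) - 1L)
  seed <- seed %||% config$seed
  tr <- with_seed(seed, sort(sample(main_idx, n_tr)))
  va <- setdiff(main_idx, tr)
  list(train = studies[tr], validation = studies[va], test = studies[test_idx])
}
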