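# Orchestration: cohort -> kinetic maps -> ROIs -> feature tables ->
# reduction -> seeded modeling protocol -> performance reports, for the two
# analyses (intratumoral+peritumoral; intratumoral-only) and the two feature
# arms (CR, DLB). The arms share every stage except feature extraction.

#' Pipeline run configuration
#'
#' @param mode `"synthetic"` (phantom cohort) or `"real"` (ingested studies).
#' @param analysis `"intra_peri"` (primary) or `"intra_only"`.
#' @param arm `"CR"`, `"DLB"` or `"both"`.
#' @param phantom a [phantom_config()] (synthetic mode).
#' @param params a [reduction_params()], or `NULL` to grid-search.
#' @param grid grid to search when `params` is `NULL` (default
#'   [reduction_grid()]).
#' @param grid_seeds seeds per grid cell for the search.
#' @param model a [model_config()].
#' @param backbone a [backbone_config()] (DLB arm).
#' @param ring_mm peritumoral ring width, mm.
#' @param levels grey levels for quantization.
#' @param output_dir directory for the report bundle, or `NULL`.
#' @param seed global seed (cohort, split, rebalancing).
#' @return object of class `run_config`.
#' @export
run_config <- function(mode = c("synthetic", "real"),
                       analysis = c("intra_peri", "intra_only"),
                       arm = c("both", "CR", "DLB"),
                       phantom = phantom_config(),
                       params = reduction_params(),
                       grid = reduction_grid(),
                       grid_seeds = 5L,
                       model = model_config(),
                       backbone = NULL,
                       ring_mm = 4,
                       levels = 128L,
                       output_dir = NULL,
                       seed = 1L) {
  structure(list(mode = match.arg(mode), analysis = match.arg(analysis),
                 arm = match.arg(arm), phantom = phantom, params = params,
                 grid = grid, grid_seeds = as.integer(grid_seeds),
                 model = model,
                 backbone = backbone %||% backbone_config(seed = seed),
                 ring_mm = ring_mm, levels = as.integer(levels),
                 output_dir = output_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Feature table for a list of studies
#'
#' Computes kinetic maps and ROIs per subject and assembles one row per
#' subject: image features (CR catalog or DLB vector, intratumoral only or
#' intratumoral+peritumoral) followed by the 11 encoded clinical covariates
#' (`clinical:` prefix).
#'
#' @param studies list of `dce_study`.
#' @param arm `"CR"` or `"DLB"`.
#' @param analysis `"intra_peri"` or `"intra_only"`.
#' @param backbone a [backbone_config()] (DLB arm).
#' @param ring_mm ring width, mm.
#' @param levels grey levels.
#' @return list with `x` (numeric matrix, rownames = subject ids) and
#'   `labels` (logical).
#' @export
extract_feature_table <- function(studies, arm = c("CR", "DLB"),
                                  analysis = c("intra_peri", "intra_only"),
                                  backbone = NULL, ring_mm = 4, levels = 128L) {
  arm <- match.arg(arm)
  analysis <- match.arg(analysis)
  if (arm == "DLB" && is.null(backbone))
    stop_named("pipeline", "DLB arm needs a backbone_config")
  catalog <- if (arm == "CR") default_cr_catalog(analysis) else NULL
  regions <- if (analysis == "intra_peri") c("I", "P") else "I"
  rows <- lapply(studies, function(st) {
    maps <- compute_kinetic_maps(st)
    rois <- build_peritumoral_ring(st$intratumoral_mask, distance = ring_mm,
                                   spacing = st$spacing)
    img <- if (arm == "CR") {
      extract_cr_vector(st, maps, rois, catalog, levels = levels)
    } else {
      extract_dlb_vector(maps, rois, backbone, regions = regions)
    }
    clin <- encode_clinical(st$clinical)
    names(clin) <- paste0("clinical:", names(clin))
    c(img, clin)
  })
  x <- do.call(rbind, rows)
  rownames(x) <- vapply(studies, `[[`, character(1), "subject_id")
  labels <- vapply(studies, `[[`, logical(1), "label")
  list(x = x, labels = labels)
}

#' Run the full pipeline
#'
#' Synthetic mode: generates the phantom cohort, splits it, extracts features
#' for the requested arm(s), reduces (fixed parameters or grid search by mean
#' validation accuracy), runs the multi-seed protocol and reports per-split
#' performance. When `output_dir` is set, writes feature tables (CSV),
#' per-arm reports and selected features (JSON), and the resolved
#' configuration.
#'
#' @param config a [run_config()].
#' @param studies optional pre-built list of `dce_study` (real mode).
#' @return list with one entry per arm: `params`, `pipeline`
#'   (a `fitted_pipeline`), `reports`, `selected`; plus `cohort` metadata.
#' @export
run_pipeline <- function(config, studies = NULL) {
  stopifnot(inherits(config, "run_config"))
  if (config$mode == "synthetic") {
    cohort <- generate_cohort(config$phantom)
    splits <- split_cohort(cohort, config$phantom,
                           train_fraction = config$phantom$n_train /
                             (config$phantom$n_train + config$phantom$n_val))
    manifest <- cohort$manifest
  } else {
    if (is.null(studies)) stop_named("pipeline", "real mode needs studies")
    stop_named("pipeline", "real mode requires a pre-split study list; see vignette")
  }
  arms <- if (config$arm == "both") c("CR", "DLB") else config$arm
  labels <- lapply(splits, function(ss) vapply(ss, `[[`, logical(1), "label"))

  results <- list()
  for (arm in arms) {
    tables <- lapply(splits, function(ss)
      extract_feature_table(ss, arm = arm, analysis = config$analysis,
                            backbone = config$backbone,
                            ring_mm = config$ring_mm, levels = config$levels)$x)
    params <- config$params
    grid_summary <- NULL
    if (is.null(params)) {
      gs <- select_reduction_params(config$grid, tables, labels,
                                    n_seeds = config$grid_seeds,
                                    model_config = config$model)
      params <- gs$params
      grid_summary <- gs$summary
    }
    red <- reduce_features(tables, labels, params, seed = config$seed)
    fit <- run_seed_protocol(red, labels, config$model)
    results[[arm]] <- list(params = params, grid_summary = grid_summary,
                           pipeline = fit, reports = fit$reports,
                           selected = fit$selected,
                           n_features_in = ncol(red$train))
  }
  out <- list(arms = results,
              cohort = list(manifest = manifest,
                            n = vapply(splits, length, integer(1))),
              config = config)
  if (!is.null(config$output_dir)) write_report_bundle(out, splits, config)
  out
}

write_report_bundle <- function(out, splits, config) {
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  for (arm in names(out$arms)) {
    res <- out$arms[[arm]]
    jsonlite::write_json(
      list(params = unclass(res$params),
           selected = res$selected,
           threshold = res$pipeline$threshold,
           winning_seed = res$pipeline$winning_seed,
           reports = lapply(res$reports, function(r) r[c(
             "auc", "sensitivity", "specificity", "ppv", "npv",
             "accuracy", "youden")])),
      file.path(config$output_dir, sprintf("report_%s.json", arm)),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  cfg <- config
  cfg$grid <- NULL
  cfg$backbone <- cfg$backbone[c("architecture_id", "tap_point", "output_dim",
                                 "weights_source", "seed")]
  jsonlite::write_json(rapply(unclass(cfg), unclass, how = "replace"),
                       file.path(config$output_dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE, null = "null")
  invisible(NULL)
}

#' Write a feature table as CSV
#'
#' Canonical feature names in the header; subjects as rows with their id and
#' label in the first two columns.
#'
#' @param table result of [extract_feature_table()].
#' @param path output CSV path.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(subject_id = rownames(table$x),
                   label = table$labels, check.names = FALSE)
  df <- cbind(df, as.data.frame(table$x, check.names = FALSE))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#' @param path CSV path.
#' @return list with `x` and `labels` as in [extract_feature_table()].
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  x <- as.matrix(df[, -(1:2), drop = FALSE])
  rownames(x) <- df$subject_id
  list(x = x, labels = as.logical(df$label))
}

#' Load one subject's study from NIfTI volumes
#'
#' Validates the five-phase contract (5 volumes, one grid, binary mask),
#' reads voxel spacing from the headers, and applies the 64-voxel ROI
#' inclusion rule: too-small ROIs return `NULL` with a message (subject
#' excluded) rather than an error.
#'
#' @param phase_paths character vector of 5 NIfTI paths (S0..S4).
#' @param mask_path NIfTI path of the binary intratumoral mask.
#' @param clinical clinical record list (see [encode_clinical()]).
#' @param label logical SLN status.
#' @param subject_id identifier.
#' @return a `dce_study`, or `NULL` if the subject is excluded.
#' @export
load_study <- function(phase_paths, mask_path, clinical, label, subject_id) {
  if (length(phase_paths) != 5L)
    stop_named("phase-count", "expected exactly 5 phase volumes, got %d",
               length(phase_paths))
  phases <- lapply(phase_paths, function(p) {
    img <- RNifti::readNifti(p)
    array(as.numeric(img), dim = dim(img))
  })
  hdr <- RNifti::niftiHeader(RNifti::readNifti(phase_paths[1]))
  spacing <- hdr$pixdim[2:4]
  mimg <- RNifti::readNifti(mask_path)
  mvals <- as.numeric(mimg)
  if (!all(mvals %in% c(0, 1)))
    stop_named("mask-binary", "mask is not binary")
  mask <- array(mvals == 1, dim = dim(mimg))
  dm <- dim(phases[[1]])
  for (p in phases)
    if (!identical(dim(p), dm)) stop_named("grid-mismatch", "phase grids differ")
  if (!identical(dim(mask), dm))
    stop_named("grid-mismatch", "mask grid differs from phases")
  if (!validate_roi(mask)) {
    message(sprintf("subject %s excluded: ROI < 64 voxels (%d)",
                    subject_id, sum(mask)))
    return(NULL)
  }
  new_dce_study(phases, spacing, mask, label, clinical, subject_id)
}

#' Save a study's volumes as NIfTI files
#'
#' @param study a `dce_study`.
#' @param dir output directory.
#' @return named list of written paths (`phases`, `mask`).
#' @export
save_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_one <- function(a, path) {
    img <- RNifti::asNifti(a)
    RNifti::pixdim(img) <- study$spacing
    RNifti::writeNifti(img, path)
    path
  }
  phase_paths <- vapply(seq_along(study$phases), function(i)
    write_one(study$phases[[i]],
              file.path(dir, sprintf("%s_phase%d.nii.gz", study$subject_id, i - 1))),
    character(1))
  mask_path <- write_one(study$intratumoral_mask + 0,
                         file.path(dir, sprintf("%s_mask.nii.gz", study$subject_id)))
  list(phases = phase_paths, mask = mask_path)
}
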