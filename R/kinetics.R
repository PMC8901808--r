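#' Kinetic ratio maps from a five-phase DCE series
#'
#' Computes the three contrast-kinetics ratio maps, in percent, from the
#' pre-contrast phase S0, first post-contrast phase S1 and last post-contrast
#' phase S4:
#' \itemize{
#'   \item wash-in  = 100 * (S1 - S0) / S0
#'   \item wash-out = 100 * (S1 - S4) / S1
#'   \item SER      = 100 * (S1 - S0) / (S4 - S0)
#' }
#' Voxels where any of the three denominators (S0, S1, S4 - S0) is zero are
#' excluded from `valid_mask` and carry `NA` in all maps; they are never
#' silently zeroed.
#'
#' @param study a `dce_study` (5 co-registered phase volumes).
#' @return object of class `kinetic_maps`: list with `wash_in`, `wash_out`,
#'   `ser` (3D percent maps, `NA` outside `valid_mask`) and `valid_mask`.
#' @export
compute_kinetic_maps <- function(study) {
  stopifnot(inherits(study, "dce_study"))
  s0 <- study$phases[[1]]
  s1 <- study$phases[[2]]
  s4 <- study$phases[[5]]
  if (!identical(dim(s0), dim(s1)) || !identical(dim(s0), dim(s4)))
    stop_named("phase-shape", "phase volumes have mismatched shapes")
  valid <- (s0 != 0) & (s1 != 0) & ((s4 - s0) != 0)
  wash_in <- 100 * (s1 - s0) / s0
  wash_out <- 100 * (s1 - s4) / s1
  ser <- 100 * (s1 - s0) / (s4 - s0)
  wash_in[!valid] <- NA_real_
  wash_out[!valid] <- NA_real_
  ser[!valid] <- NA_real_
  structure(list(wash_in = wash_in, wash_out = wash_out, ser = ser,
                 valid_mask = valid),
            class = "kinetic_maps")
}

#' Absolute resampling windows
#'
#' The fixed physical intensity windows used before grey-level quantization,
#' per map and region: intratumoral wash-in 0..640, wash-out -156..100,
#' SER -1280..1280; peritumoral wash-in 0..640, wash-out -540..100,
#' SER -1280..1280 (all percent).
#'
#' @param map_kind one of `"wash_in"`, `"wash_out"`, `"ser"`.
#' @param region_kind `"intratumoral"` or `"peritumoral"`.
#' @return object of class `resampling_window` with `lower`, `upper`.
#' @export
resampling_window <- function(map_kind = c("wash_in", "wash_out", "ser"),
                              region_kind = c("intratumoral", "peritumoral"),
                              lower = NULL, upper = NULL) {
  map_kind <- match.arg(map_kind)
  region_kind <- match.arg(region_kind)
  defaults <- list(
    intratumoral = list(wash_in = c(0, 640), wash_out = c(-156, 100),
                        ser = c(-1280, 1280)),
    peritumoral = list(wash_in = c(0, 640), wash_out = c(-540, 100),
                       ser = c(-1280, 1280)))
  w <- defaults[[region_kind]][[map_kind]]
  lower <- lower %||% w[1]
  upper <- upper %||% w[2]
  if (!(lower < upper)) stop_named("window", "window lower must be < upper")
  structure(list(map_kind = map_kind, region_kind = region_kind,
                 lower = lower, upper = upper), class = "resampling_window")
}

#' Clip a percent map into a resampling window
#'
#' Values are clipped into `[lower, upper]`; invalid (`NA`) voxels are left
#' untouched.
#'
#' @param map 3D percent map (may contain `NA`).
#' @param window a [resampling_window()].
#' @return clipped map, same shape.
#' @export
apply_window <- function(map, window) {
  stopifnot(inherits(window, "resampling_window"))
  out <- pmin(pmax(map, window$lower), window$upper)
  if (!is.null(dim(map))) dim(out) <- dim(map)
  out
}

#' Grey-level quantization of a windowed map
#'
#' Left-closed equal-width binning over the window:
#' `level(v) = min(levels - 1, floor((v - lower) / (upper - lower) * levels))`
#' so `v = lower` maps to level 0 and `v = upper` to `levels - 1`. `NA`
#' voxels stay `NA`.
#'
#' @param map windowed percent map.
#' @param window a [resampling_window()].
#' @param levels number of grey levels (default 128).
#' @return integer-valued array of levels in `0..levels-1`.
#' @export
quantize <- function(map, window, levels = 128L) {
  stopifnot(inherits(window, "resampling_window"))
  levels <- as.integer(levels)
  if (levels < 2L) stop_named("quantize", "levels must be >= 2")
  lv <- floor((map - window$lower) / (window$upper - window$lower) * levels)
  lv <- pmin(pmax(lv, 0), levels - 1L)
  if (!is.null(dim(map))) dim(lv) <- dim(map)
  lv
}
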