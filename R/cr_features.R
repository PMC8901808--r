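# Conventional radiomics: shape, first-order, GLCM, NGLDM, GLRLM, GLZLM and
# Laws texture-energy features over quantized kinetic maps.
#
# Conventions (documented in the methods vignette):
#  - texture is 3D: co-occurrence/run accumulation over the 13 unique
#    directions, zones and neighbourhoods 26-connected;
#  - grey levels are the quantized bins 0..L-1; where a feature weights by
#    grey value (NGLDM busyness, GLZLM low-grey emphasis) the 1-based value
#    level+1 is used so level 0 stays finite;
#  - matrices are normalized to sum 1 before feature computation.

# ---------------------------------------------------------------- shape ----

#' Shape features of a tumor mask
#'
#' Volume (mm^3, voxel counting), surface area (mm^2, exposed-face counting),
#' extent (volume / bounding-box volume), sphericity
#' (pi^(1/3) (6V)^(2/3) / A) and compacity (1 / sphericity). Intensities play
#' no role; shape is computed for the intratumoral ROI only.
#'
#' @param mask binary 3D volume.
#' @param spacing mm voxel pitch.
#' @return named numeric vector.
#' @export
extract_shape <- function(mask, spacing) {
  n <- sum(mask)
  if (n < 1L) stop_named("empty-mask", "shape features need a nonempty mask")
  vol <- n * prod(spacing)
  dm <- dim(mask)
  area <- 0
  face_area <- c(spacing[2] * spacing[3], spacing[1] * spacing[3],
                 spacing[1] * spacing[2])
  for (ax in 1:3) {
    for (s in c(-1L, 1L)) {
      d <- c(0L, 0L, 0L); d[ax] <- s
      r <- offset_ranges(dm, d)
      inner <- mask
      covered <- array(FALSE, dim = dm)
      if (!is.null(r))
        covered[r$a[[1]], r$a[[2]], r$a[[3]]] <- mask[r$b[[1]], r$b[[2]], r$b[[3]]]
      area <- area + sum(mask & !covered) * face_area[ax]
    }
  }
  box <- bounding_box(mask)
  bb_vol <- prod(vapply(box, length, integer(1))) * prod(spacing)
  sph <- pi^(1 / 3) * (6 * vol)^(2 / 3) / area
  c(shape_volume_mm3 = vol,
    shape_surface_mm2 = area,
    shape_extent = vol / bb_vol,
    shape_sphericity = sph,
    shape_compacity = 1 / sph)
}

# ---------------------------------------------------------- first order ----

#' First-order (histogram) features over a quantized ROI
#'
#' Mean, variance (population), skewness, kurtosis (non-excess), histogram
#' entropy (log2) and energy (sum of squared level probabilities) over the
#' in-ROI grey levels. Degenerate (constant) regions have skewness and
#' kurtosis 0 by convention.
#'
#' @param quantized grey-level volume (`NA` = invalid voxel).
#' @param roi binary volume.
#' @return named numeric vector.
#' @export
extract_first_order <- function(quantized, roi) {
  x <- quantized[roi & !is.na(quantized)]
  if (length(x) < 2L)
    stop_named("first-order", "need >= 2 in-ROI voxels for variance-based stats")
  p <- tabulate(x + 1L) / length(x)
  c(fo_mean = mean(x),
    fo_variance = mean((x - mean(x))^2),
    fo_skewness = moment_skewness(x),
    fo_kurtosis = moment_kurtosis(x),
    fo_entropy_log2 = entropy_log2(p),
    fo_energy = sum(p^2))
}

# ------------------------------------------------------------------ GLCM ----

#' Grey-level co-occurrence matrix
#'
#' Symmetric GLCM accumulated over the 13 unique 3D directions at the given
#' voxel distance, counting only pairs with both voxels in the ROI (and
#' valid); each pair contributes to (i, j) and (j, i). Normalized to sum 1.
#'
#' @param quantized grey-level volume (`NA` = invalid).
#' @param roi binary volume.
#' @param distance pair distance in voxels (default 1).
#' @param levels matrix size; defaults to max in-ROI level + 1.
#' @return `levels x levels` probability matrix.
#' @export
glcm_matrix <- function(quantized, roi, distance = 1L, levels = NULL) {
  box <- bounding_box(roi)
  q <- crop_to_box(quantized, box)
  r <- crop_to_box(roi, box)
  ok <- r & !is.na(q)
  if (!any(ok)) stop_named("glcm", "no valid in-ROI voxels")
  L <- as.integer(levels %||% (max(q[ok]) + 1L))
  counts <- numeric(L * L)
  dm <- dim(q)
  for (d in DIRECTIONS_13) {
    rg <- offset_ranges(dm, d * as.integer(distance))
    if (is.null(rg)) next
    a <- q[rg$a[[1]], rg$a[[2]], rg$a[[3]]]
    b <- q[rg$b[[1]], rg$b[[2]], rg$b[[3]]]
    sel <- ok[rg$a[[1]], rg$a[[2]], rg$a[[3]]] & ok[rg$b[[1]], rg$b[[2]], rg$b[[3]]]
    if (!any(sel)) next
    av <- as.integer(a[sel])
    bv <- as.integer(b[sel])
    counts <- counts + tabulate(av * L + bv + 1L, nbins = L * L) +
      tabulate(bv * L + av + 1L, nbins = L * L)
  }
  tot <- sum(counts)
  if (tot == 0) stop_named("glcm-no-pairs", "no valid co-occurring pairs in ROI")
  matrix(counts / tot, L, L)
}

glcm_features <- function(P) {
  L <- nrow(P)
  i <- matrix(rep(0:(L - 1), L), L, L)        # row level
  j <- t(i)
  pi_ <- rowSums(P)
  mu_i <- sum((0:(L - 1)) * pi_)
  sd_i <- sqrt(sum(((0:(L - 1)) - mu_i)^2 * pi_))
  corr <- if (sd_i > 0)
    sum((i - mu_i) * (j - mu_i) * P) / sd_i^2 else 0
  c(glcm_entropy_log2 = entropy_log2(as.numeric(P)),
    glcm_energy = sum(P^2),
    glcm_contrast = sum((i - j)^2 * P),
    glcm_correlation = corr,
    glcm_homogeneity = sum(P / (1 + abs(i - j))),
    glcm_dissimilarity = sum(abs(i - j) * P))
}

#' GLCM features over a quantized ROI
#' @inheritParams glcm_matrix
#' @return named numeric vector.
#' @export
extract_glcm <- function(quantized, roi, distance = 1L, levels = NULL) {
  glcm_features(glcm_matrix(quantized, roi, distance, levels))
}

# ----------------------------------------------------------------- NGLDM ----

#' Neighbourhood grey-level difference accumulation
#'
#' For every in-ROI voxel with at least one 26-connected in-ROI neighbour,
#' accumulates the absolute difference between the voxel level and the mean
#' level of its in-ROI neighbours, per grey level.
#'
#' @inheritParams glcm_matrix
#' @return data.frame with `level`, `n` (voxel count) and `s` (summed
#'   absolute difference), one row per occupied level.
#' @export
ngldm_table <- function(quantized, roi) {
  box <- bounding_box(roi)
  q <- crop_to_box(quantized, box)
  r <- crop_to_box(roi, box)
  ok <- r & !is.na(q)
  dm <- dim(q)
  q0 <- q
  q0[!ok] <- 0
  nsum <- array(0, dim = dm)
  ncnt <- array(0L, dim = dm)
  for (d in NEIGHBOURS_26) {
    rg <- offset_ranges(dm, d)
    if (is.null(rg)) next
    nb_ok <- ok[rg$b[[1]], rg$b[[2]], rg$b[[3]]]
    nsum[rg$a[[1]], rg$a[[2]], rg$a[[3]]] <-
      nsum[rg$a[[1]], rg$a[[2]], rg$a[[3]]] + q0[rg$b[[1]], rg$b[[2]], rg$b[[3]]]
    ncnt[rg$a[[1]], rg$a[[2]], rg$a[[3]]] <-
      ncnt[rg$a[[1]], rg$a[[2]], rg$a[[3]]] + nb_ok
  }
  use <- ok & ncnt >= 1L
  if (!any(use)) stop_named("ngldm", "no in-ROI voxel has an in-ROI neighbour")
  lev <- as.integer(q[use])
  diffs <- abs(q[use] - nsum[use] / ncnt[use])
  n_by <- tapply(rep(1L, length(lev)), lev, sum)
  s_by <- tapply(diffs, lev, sum)
  data.frame(level = as.integer(names(n_by)),
             n = as.integer(n_by), s = as.numeric(s_by))
}

#' NGLDM features (coarseness, contrast, busyness)
#'
#' Definitions follow the neighbourhood grey-tone difference formulation with
#' 1-based grey values and an epsilon guard (1e-6) keeping constant regions
#' finite: a constant ROI has contrast 0 and coarseness at the guarded
#' maximum 1e6.
#'
#' @inheritParams glcm_matrix
#' @return named numeric vector.
#' @export
extract_ngldm <- function(quantized, roi) {
  tb <- ngldm_table(quantized, roi)
  N <- sum(tb$n)
  p <- tb$n / N
  g <- tb$level + 1
  Ng <- nrow(tb)
  eps <- 1e-6
  coarseness <- 1 / (sum(p * tb$s) + eps)
  if (Ng >= 2L) {
    pij <- outer(p, p)
    gd2 <- outer(g, g, function(a, b) (a - b)^2)
    contrast <- sum(pij * gd2) / (Ng * (Ng - 1)) * sum(tb$s) / N
    gp <- g * p
    busy_den <- sum(abs(outer(gp, gp, `-`)))
    busyness <- sum(p * tb$s) / (busy_den + eps)
  } else {
    contrast <- 0
    busyness <- 0
  }
  c(ngldm_coarseness = coarseness,
    ngldm_contrast = contrast,
    ngldm_busyness = busyness)
}

# ----------------------------------------------------------------- GLRLM ----

#' Grey-level run-length matrix
#'
#' Maximal runs of equal grey level accumulated over the 13 unique 3D
#' directions; runs are confined to the ROI (an out-of-ROI or invalid voxel
#' breaks a run).
#'
#' @inheritParams glcm_matrix
#' @param levels number of grey levels (rows); defaults to max level + 1.
#' @return `levels x max_run` count matrix (grey level by run length).
#' @export
glrlm_matrix <- function(quantized, roi, levels = NULL) {
  box <- bounding_box(roi)
  q <- crop_to_box(quantized, box)
  r <- crop_to_box(roi, box)
  ok <- r & !is.na(q)
  if (!any(ok)) stop_named("glrlm", "no valid in-ROI voxels")
  L <- as.integer(levels %||% (max(q[ok]) + 1L))
  dm <- dim(q)
  coords <- as.matrix(expand.grid(x = seq_len(dm[1]), y = seq_len(dm[2]),
                                  z = seq_len(dm[3])))
  val <- as.integer(q)
  val[!ok] <- NA_integer_
  runs_g <- integer(0)
  runs_r <- integer(0)
  for (d in DIRECTIONS_13) {
    ax0 <- which(d != 0)[1]
    t <- coords[, ax0]                       # increases along the direction
    key <- coords - outer(t, d)              # line anchor (3 components)
    ord <- order(key[, 1], key[, 2], key[, 3], t)
    v <- val[ord]
    k1 <- key[ord, 1]; k2 <- key[ord, 2]; k3 <- key[ord, 3]
    n <- length(v)
    prev_v <- c(NA_integer_, v[-n])
    newline <- c(TRUE, k1[-1] != k1[-n] | k2[-1] != k2[-n] | k3[-1] != k3[-n])
    same <- !newline & !is.na(v) & !is.na(prev_v) & v == prev_v
    starts <- which(!same)
    lens <- diff(c(starts, n + 1L))
    vals <- v[starts]
    keep <- !is.na(vals)
    runs_g <- c(runs_g, vals[keep])
    runs_r <- c(runs_r, lens[keep])
  }
  R <- matrix(0, nrow = L, ncol = max(runs_r))
  for (i in seq_along(runs_g))
    R[runs_g[i] + 1L, runs_r[i]] <- R[runs_g[i] + 1L, runs_r[i]] + 1
  R
}

#' GLRLM features (SRE, LRE, GLNU, RLNU, RP)
#'
#' Run percentage is the total run count divided by 13 times the ROI voxel
#' count (13 scan directions), so an isolated voxel has RP 1.
#'
#' @inheritParams glrlm_matrix
#' @return named numeric vector.
#' @export
extract_glrlm <- function(quantized, roi, levels = NULL) {
  R <- glrlm_matrix(quantized, roi, levels)
  n_vox <- sum(roi & !is.na(quantized))
  rl <- seq_len(ncol(R))
  Nr <- sum(R)
  rsum <- colSums(R)
  gsum <- rowSums(R)
  c(glrlm_sre = sum(sweep(R, 2, rl^2, `/`)) / Nr,
    glrlm_lre = sum(sweep(R, 2, rl^2, `*`)) / Nr,
    glrlm_glnu = sum(gsum^2) / Nr,
    glrlm_rlnu = sum(rsum^2) / Nr,
    glrlm_rp = Nr / (13 * n_vox))
}

# ----------------------------------------------------------------- GLZLM ----

#' Grey-level zone-length matrix
#'
#' Zones are 26-connected components of equal grey level within the ROI.
#'
#' @inheritParams glrlm_matrix
#' @return `levels x max_zone_size` count matrix.
#' @export
glzlm_matrix <- function(quantized, roi, levels = NULL) {
  box <- bounding_box(roi)
  q <- crop_to_box(quantized, box)
  r <- crop_to_box(roi, box)
  ok <- r & !is.na(q)
  if (!any(ok)) stop_named("glzlm", "no valid in-ROI voxels")
  L <- as.integer(levels %||% (max(q[ok]) + 1L))
  dm <- dim(q)
  lin <- array(seq_len(prod(dm)), dim = dm)
  from <- integer(0)
  to <- integer(0)
  for (d in DIRECTIONS_13) {
    rg <- offset_ranges(dm, d)
    if (is.null(rg)) next
    qa <- q[rg$a[[1]], rg$a[[2]], rg$a[[3]]]
    qb <- q[rg$b[[1]], rg$b[[2]], rg$b[[3]]]
    sel <- ok[rg$a[[1]], rg$a[[2]], rg$a[[3]]] &
      ok[rg$b[[1]], rg$b[[2]], rg$b[[3]]] & (qa == qb)
    sel[is.na(sel)] <- FALSE
    if (!any(sel)) next
    from <- c(from, lin[rg$a[[1]], rg$a[[2]], rg$a[[3]]][sel])
    to <- c(to, lin[rg$b[[1]], rg$b[[2]], rg$b[[3]]][sel])
  }
  nodes <- which(ok)
  g <- igraph::graph_from_data_frame(
    d = data.frame(from = as.character(from), to = as.character(to)),
    directed = FALSE,
    vertices = data.frame(name = as.character(nodes)))
  comp <- igraph::components(g)
  memb <- comp$membership
  zone_size <- as.integer(table(memb))
  zone_level <- as.integer(tapply(q[nodes], memb, function(v) v[1]))
  Z <- matrix(0, nrow = L, ncol = max(zone_size))
  for (i in seq_along(zone_size))
    Z[zone_level[i] + 1L, zone_size[i]] <- Z[zone_level[i] + 1L, zone_size[i]] + 1
  Z
}

#' GLZLM features (SZE, LZE, ZP, LZLGE)
#'
#' Zone percentage is the zone count over the ROI voxel count; long-zone
#' low-grey-level emphasis weights by squared zone size over squared 1-based
#' grey value.
#'
#' @inheritParams glrlm_matrix
#' @return named numeric vector.
#' @export
extract_glzlm <- function(quantized, roi, levels = NULL) {
  Z <- glzlm_matrix(quantized, roi, levels)
  n_vox <- sum(roi & !is.na(quantized))
  s <- seq_len(ncol(Z))
  gsq <- (seq_len(nrow(Z)))^2            # 1-based grey value squared
  Nz <- sum(Z)
  c(glzlm_sze = sum(sweep(Z, 2, s^2, `/`)) / Nz,
    glzlm_lze = sum(sweep(Z, 2, s^2, `*`)) / Nz,
    glzlm_zp = Nz / n_vox,
    glzlm_lzlge = sum(sweep(sweep(Z, 2, s^2, `*`), 1, gsq, `/`)) / Nz)
}

# ------------------------------------------------------------------ Laws ----

LAWS_KERNELS <- list(
  L5 = c(1, 4, 6, 4, 1),
  E5 = c(-1, -2, 0, 2, 1),
  S5 = c(-1, 0, 2, 0, -1),
  W5 = c(-1, 2, 0, -2, 1),
  R5 = c(1, -4, 6, -4, 1))

# filter k in 1..25, row-major over (L5, E5, S5, W5, R5) x (L5, E5, S5, W5, R5)
laws_filter_pair <- function(k) {
  i <- (k - 1) %/% 5 + 1
  j <- (k - 1) %% 5 + 1
  list(row = LAWS_KERNELS[[i]], col = LAWS_KERNELS[[j]])
}

# zero-padded same-size 2D correlation with separable 5-tap kernels
correlate2d_sep <- function(m, kr, kc) {
  tmp <- shift_weighted_sum(m, kr, along = 1L)
  shift_weighted_sum(tmp, kc, along = 2L)
}

shift_weighted_sum <- function(m, k, along) {
  half <- (length(k) - 1L) / 2L
  out <- matrix(0, nrow(m), ncol(m))
  n <- if (along == 1L) nrow(m) else ncol(m)
  for (t in seq_along(k)) {
    off <- t - half - 1L
    src_from <- max(1L, 1L + off)
    src_to <- min(n, n + off)
    if (src_from > src_to) next
    dst_from <- src_from - off
    dst_to <- src_to - off
    if (along == 1L) {
      out[dst_from:dst_to, ] <- out[dst_from:dst_to, ] + k[t] * m[src_from:src_to, ]
    } else {
      out[, dst_from:dst_to] <- out[, dst_from:dst_to] + k[t] * m[, src_from:src_to]
    }
  }
  out
}

#' Laws texture-energy features
#'
#' Responses of the 25 outer-product filters of the five 5-tap Laws kernels
#' (L5, E5, S5, W5, R5; numbered 1..25 row-major), computed by same-size
#' zero-padded 2D correlation on each slice of the windowed (unquantized)
#' percent map; invalid voxels enter the convolution as 0. In-ROI responses
#' are pooled across slices and summarized as `laws_energy_k` (mean squared
#' response) and `laws_skewness_k`.
#'
#' @param map windowed percent map (`NA` = invalid).
#' @param roi binary volume.
#' @param filters integer subset of 1..25 (default all).
#' @return named numeric vector (energy then skewness per filter).
#' @export
extract_laws <- function(map, roi, filters = 1:25) {
  if (sum(roi) < 1L) stop_named("laws", "ROI intersects no slice")
  dm <- dim(map)
  zs <- which(apply(roi, 3, any))
  resp <- vector("list", length(filters))
  names(resp) <- as.character(filters)
  for (fk in seq_along(filters)) resp[[fk]] <- numeric(0)
  for (z in zs) {
    sl <- map[, , z]
    sl[is.na(sl)] <- 0
    rsl <- roi[, , z]
    rows_done <- list()
    for (fk in seq_along(filters)) {
      pair <- laws_filter_pair(filters[fk])
      rkey <- paste(pair$row, collapse = ",")
      if (is.null(rows_done[[rkey]]))
        rows_done[[rkey]] <- shift_weighted_sum(sl, pair$row, along = 1L)
      out <- shift_weighted_sum(rows_done[[rkey]], pair$col, along = 2L)
      resp[[fk]] <- c(resp[[fk]], out[rsl])
    }
  }
  en <- vapply(resp, function(v) mean(v^2), numeric(1))
  sk <- vapply(resp, moment_skewness, numeric(1))
  out <- c(en, sk)
  names(out) <- c(paste0("laws_energy_", filters), paste0("laws_skewness_", filters))
  out
}

# --------------------------------------------------------------- catalog ----

#' Default conventional-radiomics feature catalog
#'
#' The catalog pins which (family, statistic, map, region) combinations make
#' up a feature row. Defaults give 93 intratumoral features (5 shape + 18
#' first-order + 18 GLCM + 9 NGLDM + 15 GLRLM + 12 GLZLM + 16 Laws) and, for
#' the intratumoral+peritumoral analysis, 53 peritumoral features (18
#' first-order + 18 GLCM + 9 NGLDM + 8 Laws), 146 total. The Laws subsets
#' favour the filters most often reported for this task (Energy_4, Energy_8,
#' Skewness_5, Skewness_7, Skewness_9) with a fixed deterministic fill.
#'
#' @param analysis `"intra_peri"` (default) or `"intra_only"`.
#' @return data.frame with columns `family`, `map`, `region`, `feature`,
#'   `name`; class `cr_catalog`.
#' @export
default_cr_catalog <- function(analysis = c("intra_peri", "intra_only")) {
  analysis <- match.arg(analysis)
  maps <- c("wash_in", "wash_out", "ser")
  fam_feats <- list(
    firstorder = c("fo_mean", "fo_variance", "fo_skewness", "fo_kurtosis",
                   "fo_entropy_log2", "fo_energy"),
    glcm = c("glcm_entropy_log2", "glcm_energy", "glcm_contrast",
             "glcm_correlation", "glcm_homogeneity", "glcm_dissimilarity"),
    ngldm = c("ngldm_coarseness", "ngldm_contrast", "ngldm_busyness"),
    glrlm = c("glrlm_sre", "glrlm_lre", "glrlm_glnu", "glrlm_rlnu", "glrlm_rp"),
    glzlm = c("glzlm_sze", "glzlm_lze", "glzlm_zp", "glzlm_lzlge"))
  rows <- list()
  add <- function(family, map, region, feature) {
    rows[[length(rows) + 1L]] <<- data.frame(
      family = family, map = map, region = region, feature = feature,
      stringsAsFactors = FALSE)
  }
  # intratumoral: shape + full matrix families + pinned Laws 16
  for (f in names(extract_shape(array(TRUE, c(1, 1, 1)), c(1, 1, 1))))
    add("shape", "none", "I", f)
  for (fam in names(fam_feats))
    for (m in maps)
      for (ft in fam_feats[[fam]])
        add(fam, m, "I", ft)
  laws_intra <- rbind(
    expand.grid(map = maps,
                feature = c("laws_energy_4", "laws_energy_8", "laws_skewness_5",
                            "laws_skewness_7", "laws_skewness_9"),
                stringsAsFactors = FALSE),
    data.frame(map = "wash_in", feature = "laws_energy_1"))
  for (i in seq_len(nrow(laws_intra)))
    add("laws", laws_intra$map[i], "I", laws_intra$feature[i])
  # peritumoral: first-order + GLCM + NGLDM + pinned Laws 8
  if (analysis == "intra_peri") {
    for (fam in c("firstorder", "glcm", "ngldm"))
      for (m in maps)
        for (ft in fam_feats[[fam]])
          add(fam, m, "P", ft)
    laws_peri <- rbind(
      expand.grid(map = maps, feature = c("laws_energy_8", "laws_skewness_9"),
                  stringsAsFactors = FALSE),
      data.frame(map = c("wash_in", "wash_out"),
                 feature = c("laws_energy_4", "laws_skewness_5")))
    for (i in seq_len(nrow(laws_peri)))
      add("laws", laws_peri$map[i], "P", laws_peri$feature[i])
  }
  cat_df <- do.call(rbind, rows)
  cat_df$name <- ifelse(
    cat_df$family == "shape",
    paste0("CR:I:", cat_df$feature),
    paste0("CR:", cat_df$region, ":", cat_df$map, ":", cat_df$feature))
  stopifnot(!anyDuplicated(cat_df$name))
  class(cat_df) <- c("cr_catalog", "data.frame")
  cat_df
}

# ---------------------------------------------------------------- vector ----

#' Conventional radiomics feature row for one subject
#'
#' Applies the region-specific absolute-resampling windows, quantizes to
#' `levels` grey levels, and evaluates every catalog entry. Shape features
#' are intratumoral only. Any family failure is reported with its
#' (family, map, region).
#'
#' @param study a `dce_study`.
#' @param maps a `kinetic_maps` for the study.
#' @param rois a `roi_pair`.
#' @param catalog a catalog from [default_cr_catalog()].
#' @param levels grey levels for quantization (default 128).
#' @return named numeric vector following the catalog order.
#' @export
extract_cr_vector <- function(study, maps, rois, catalog = default_cr_catalog(),
                              levels = 128L) {
  regions <- list(I = rois$intratumoral, P = rois$peritumoral)
  region_kind <- c(I = "intratumoral", P = "peritumoral")
  out <- setNames(rep(NA_real_, nrow(catalog)), catalog$name)

  if (any(catalog$family == "shape")) {
    sh <- extract_shape(rois$intratumoral, study$spacing)
    sel <- catalog$family == "shape"
    out[sel] <- sh[catalog$feature[sel]]
  }

  for (reg in intersect(c("I", "P"), unique(catalog$region))) {
    roi <- regions[[reg]]
    for (m in intersect(c("wash_in", "wash_out", "ser"), unique(catalog$map))) {
      sub <- catalog[catalog$region == reg & catalog$map == m &
                       catalog$family != "shape", , drop = FALSE]
      if (nrow(sub) == 0L) next
      win <- resampling_window(m, region_kind[[reg]])
      windowed <- apply_window(maps[[m]], win)
      qv <- quantize(windowed, win, levels)
      vals <- tryCatch({
        v <- c()
        fams <- unique(sub$family)
        if ("firstorder" %in% fams) v <- c(v, extract_first_order(qv, roi))
        if ("glcm" %in% fams) v <- c(v, extract_glcm(qv, roi, levels = levels))
        if ("ngldm" %in% fams) v <- c(v, extract_ngldm(qv, roi))
        if ("glrlm" %in% fams) v <- c(v, extract_glrlm(qv, roi, levels = levels))
        if ("glzlm" %in% fams) v <- c(v, extract_glzlm(qv, roi, levels = levels))
        if ("laws" %in% fams) {
          ks <- sort(unique(as.integer(sub("^laws_(energy|skewness)_", "",
                                           sub$feature[sub$family == "laws"]))))
          v <- c(v, extract_laws(windowed, roi, filters = ks))
        }
        v
      }, error = function(e)
        stop_named("cr-family", "extraction failed for (%s, %s, %s): %s",
                   paste(unique(sub$family), collapse = "/"), m,
                   region_kind[[reg]], conditionMessage(e)))
      out[sub$name] <- vals[sub$feature]
    }
  }
  if (anyNA(out))
    stop_named("cr-vector", "catalog entries unresolved: %s",
               paste(head(names(out)[is.na(out)], 5), collapse = ", "))
  out
}
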