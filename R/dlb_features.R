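# Deep-learning-based features: masked kinetic maps are rendered as
# 224x224x3 slice tensors (channels wash-in, wash-out, SER, values 0..255)
# and pushed through a frozen convolutional backbone; the activations of the
# last fully connected layer (one 1000-vector per slice) are averaged across
# slices into one subject vector. The backbone is pluggable behind a single
# forward-pass contract; no weight is ever updated.

#' Frozen backbone configuration
#'
#' `weights_source = "random_seeded"` builds a small frozen convolutional
#' network with seeded random weights (deterministic, download-free); it
#' exercises the identical plumbing as a pretrained backbone and is the
#' default for synthetic studies. `weights_source = "pretrained"` loads a
#' user-supplied weight file for a canonical 16-layer VGG-style network and
#' errors if none is given.
#'
#' @param architecture_id backbone family label (default `"vgg16"`).
#' @param tap_point layer tapped for features; only the pre-softmax last
#'   fully connected layer (`"fc"`) is supported.
#' @param output_dim width of the tapped layer (default 1000).
#' @param weights_source `"random_seeded"` or `"pretrained"`.
#' @param seed weight seed for `random_seeded`.
#' @param weights_path path to weights for `pretrained`.
#' @return object of class `backbone_config` with materialized frozen weights.
#' @export
backbone_config <- function(architecture_id = "vgg16",
                            tap_point = "fc",
                            output_dim = 1000L,
                            weights_source = c("random_seeded", "pretrained"),
                            seed = 1L,
                            weights_path = NULL) {
  weights_source <- match.arg(weights_source)
  if (!identical(tap_point, "fc"))
    stop_named("backbone-tap", "unsupported tap point '%s'", tap_point)
  output_dim <- as.integer(output_dim)
  if (weights_source == "pretrained") {
    if (is.null(weights_path) || !file.exists(weights_path))
      stop_named("backbone-weights",
                 "pretrained weights require an existing weights_path")
    stop_named("backbone-weights",
               "loading external pretrained weights is not implemented in this build")
  }
  weights <- with_seed(as.integer(seed), random_backbone_weights(output_dim))
  structure(list(architecture_id = architecture_id, tap_point = tap_point,
                 output_dim = output_dim, weights_source = weights_source,
                 seed = as.integer(seed), weights = weights),
            class = "backbone_config")
}

# Small frozen convnet: 4x4 average pool -> 5x5 conv (3->8, stride 2, ReLU)
# -> 2x2 max pool -> 3x3 conv (8->16, stride 1, ReLU) -> 2x2 max pool ->
# flatten -> fully connected to output_dim. He-style init.
random_backbone_weights <- function(output_dim) {
  w1 <- array(rnorm(5 * 5 * 3 * 8, sd = sqrt(2 / (5 * 5 * 3))), c(5, 5, 3, 8))
  b1 <- rnorm(8, sd = 0.1)
  w2 <- array(rnorm(3 * 3 * 8 * 16, sd = sqrt(2 / (3 * 3 * 8))), c(3, 3, 8, 16))
  b2 <- rnorm(16, sd = 0.1)
  flat_dim <- 7 * 7 * 16
  wf <- matrix(rnorm(flat_dim * output_dim, sd = sqrt(1 / flat_dim)),
               nrow = flat_dim, ncol = output_dim)
  bf <- rnorm(output_dim, sd = 0.1)
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2, wf = wf, bf = bf)
}

#' Render masked kinetic maps as backbone input tensors
#'
#' Per channel (wash-in, wash-out, SER): zero outside the ROI, clip into the
#' channel's absolute-resampling window, map affinely to 0..1 and multiply by
#' 255; invalid voxels are treated as background 0 before the mapping. Note
#' the background 0 passes through the same affine map, so channels whose
#' window has a negative lower bound carry a nonzero background value by
#' design. Each ROI-intersecting slice is cropped to `size x size` at the ROI
#' centroid.
#'
#' @param maps a `kinetic_maps`.
#' @param roi binary volume (intratumoral or peritumoral).
#' @param region_kind window set to use, `"intratumoral"` or `"peritumoral"`.
#' @param size tensor edge (default 224).
#' @return list of `size x size x 3` arrays, one per ROI-intersecting slice,
#'   in slice order.
#' @export
preprocess_slices <- function(maps, roi, region_kind = "intratumoral",
                              size = 224L) {
  if (sum(roi) < 1L) stop_named("empty-mask", "ROI has no voxels")
  channels <- c("wash_in", "wash_out", "ser")
  planes <- vector("list", 3L)
  for (ci in seq_along(channels)) {
    win <- resampling_window(channels[ci], region_kind)
    if (win$upper - win$lower <= 0) stop_named("window", "zero-width window")
    m <- maps[[channels[ci]]]
    m[is.na(m)] <- 0
    m <- apply_mask(m, roi)
    m <- apply_window(m, win)
    m <- (m - win$lower) / (win$upper - win$lower) * 255
    planes[[ci]] <- crop_window(m, roi, size = size)
  }
  zs <- planes[[1]]$slice_index
  lapply(seq_along(zs), function(si) {
    a <- array(0, dim = c(size, size, 3L))
    for (ci in 1:3) a[, , ci] <- planes[[ci]]$slices[[si]]
    a
  })
}

#' Forward pass of the frozen backbone for one slice tensor
#'
#' Deterministic: the same tensor and backbone always give the same vector.
#'
#' @param tensor `224 x 224 x 3` array, values in 0..255.
#' @param backbone a [backbone_config()].
#' @return numeric feature vector of length `output_dim`.
#' @export
extract_slice_features <- function(tensor, backbone) {
  stopifnot(inherits(backbone, "backbone_config"))
  dm <- dim(tensor)
  if (length(dm) != 3L || dm[1] != 224L || dm[2] != 224L || dm[3] != 3L)
    stop_named("tensor-shape", "expected a 224x224x3 tensor")
  w <- backbone$weights
  x <- avg_pool(tensor, 4L)                     # 56x56x3
  x <- conv2d(x, w$w1, w$b1, stride = 2L)       # 28x28x8
  x <- pmax(x, 0)
  x <- max_pool(x, 2L)                          # 14x14x8
  x <- conv2d(x, w$w2, w$b2, stride = 1L)       # 14x14x16
  x <- pmax(x, 0)
  x <- max_pool(x, 2L)                          # 7x7x16 = 784
  v <- as.numeric(x)
  as.numeric(crossprod(w$wf, v) + w$bf)
}

avg_pool <- function(x, k) {
  dm <- dim(x)
  no <- dm[1:2] %/% k
  out <- array(0, c(no, dm[3]))
  for (c_ in seq_len(dm[3])) {
    m <- x[seq_len(no[1] * k), seq_len(no[2] * k), c_]
    m <- array(m, c(k, no[1], k, no[2]))
    out[, , c_] <- apply(m, c(2, 4), mean)
  }
  out
}

max_pool <- function(x, k) {
  dm <- dim(x)
  no <- dm[1:2] %/% k
  out <- array(0, c(no, dm[3]))
  for (c_ in seq_len(dm[3])) {
    m <- x[seq_len(no[1] * k), seq_len(no[2] * k), c_]
    m <- array(m, c(k, no[1], k, no[2]))
    out[, , c_] <- apply(m, c(2, 4), max)
  }
  out
}

# 'same'-style strided 2D convolution (correlation) via patch matrices.
conv2d <- function(x, w, b, stride = 1L) {
  kh <- dim(w)[1]; kw <- dim(w)[2]; cin <- dim(w)[3]; cout <- dim(w)[4]
  dm <- dim(x)
  ph <- (kh - 1L) %/% 2L
  pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(dm[1] + 2 * ph, dm[2] + 2 * pw, cin))
  xp[ph + seq_len(dm[1]), pw + seq_len(dm[2]), ] <- x
  oh <- (dm[1] - 1L) %/% stride + 1L
  ow <- (dm[2] - 1L) %/% stride + 1L
  ox <- (seq_len(oh) - 1L) * stride + 1L
  oy <- (seq_len(ow) - 1L) * stride + 1L
  patches <- matrix(0, oh * ow, kh * kw * cin)
  col <- 1L
  for (c_ in seq_len(cin)) {
    for (j in seq_len(kw)) {
      for (i in seq_len(kh)) {
        patches[, col] <- as.numeric(xp[ox + i - 1L, oy + j - 1L, c_])
        col <- col + 1L
      }
    }
  }
  wm <- matrix(w, nrow = kh * kw * cin, ncol = cout)
  out <- patches %*% wm
  out <- sweep(out, 2, b, `+`)
  array(out, c(oh, ow, cout))
}

#' Average per-slice feature vectors into one subject vector
#'
#' @param rows list of equal-length numeric vectors (one per slice).
#' @return element-wise mean vector.
#' @export
aggregate_slices <- function(rows) {
  if (length(rows) == 0L) stop_named("aggregate", "no slice vectors to aggregate")
  lens <- vapply(rows, length, integer(1))
  if (length(unique(lens)) != 1L)
    stop_named("aggregate", "ragged slice vectors")
  colMeans(do.call(rbind, rows))
}

#' DLB feature row for one subject
#'
#' Runs preprocessing, the frozen forward pass per slice, and slice
#' averaging, per requested region; names are `DLB:<I|P>:fc:<index>`.
#'
#' @param maps a `kinetic_maps`.
#' @param rois a `roi_pair`.
#' @param backbone a [backbone_config()].
#' @param regions character subset of `c("I", "P")`.
#' @return named numeric vector.
#' @export
extract_dlb_vector <- function(maps, rois, backbone, regions = c("I", "P")) {
  roi_by <- list(I = rois$intratumoral, P = rois$peritumoral)
  kind_by <- c(I = "intratumoral", P = "peritumoral")
  out <- c()
  for (reg in regions) {
    tensors <- preprocess_slices(maps, roi_by[[reg]], kind_by[[reg]])
    feats <- lapply(tensors, extract_slice_features, backbone = backbone)
    v <- aggregate_slices(feats)
    names(v) <- sprintf("DLB:%s:fc:%04d", reg, seq_along(v))
    out <- c(out, v)
  }
  out
}
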