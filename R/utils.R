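# Internal helpers shared across modules.

#' @importFrom stats rnorm runif rbinom sd var cor prcomp wilcox.test glm
#'   binomial predict quantile plogis qlogis setNames dist coef filter
#' @importFrom utils head tail modifyList
NULL

# Evaluate `code` under a fixed RNG seed, restoring caller RNG state.
with_seed <- function(seed, code) {
  withr::with_seed(seed, code)
}

stop_named <- function(rule, ...) {
  stop(sprintf("[%s] %s", rule, sprintf(...)), call. = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Index ranges for pairing voxels of a 3D array with their neighbour at
# integer offset d = c(dx, dy, dz): returns NULL if no overlap, else a
# list of two index-grid lists usable with array indexing.
offset_ranges <- function(dm, d) {
  r1 <- vector("list", 3L)
  r2 <- vector("list", 3L)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      from <- 1L
      to <- dm[ax] - d[ax]
    } else {
      from <- 1L - d[ax]
      to <- dm[ax]
    }
    if (to < from) return(NULL)
    r1[[ax]] <- from:to
    r2[[ax]] <- (from + d[ax]):(to + d[ax])
  }
  list(a = r1, b = r2)
}

# The 13 unique 3D direction offsets (first nonzero component positive).
DIRECTIONS_13 <- list(
  c(1L, 0L, 0L), c(0L, 1L, 0L), c(0L, 0L, 1L),
  c(1L, 1L, 0L), c(1L, -1L, 0L),
  c(1L, 0L, 1L), c(1L, 0L, -1L),
  c(0L, 1L, 1L), c(0L, 1L, -1L),
  c(1L, 1L, 1L), c(1L, 1L, -1L), c(1L, -1L, 1L), c(1L, -1L, -1L)
)

# All 26 neighbour offsets.
NEIGHBOURS_26 <- {
  g <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  g <- g[!(g$dx == 0 & g$dy == 0 & g$dz == 0), ]
  lapply(seq_len(nrow(g)), function(i) as.integer(unlist(g[i, ])))
}

# Tight bounding box of a logical 3D array; returns list of axis ranges.
bounding_box <- function(mask, margin = 0L) {
  stopifnot(length(dim(mask)) == 3L)
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) == 0L) stop_named("empty-mask", "mask has no voxels")
  dm <- dim(mask)
  lapply(1:3, function(ax) {
    lo <- max(1L, min(idx[, ax]) - margin)
    hi <- min(dm[ax], max(idx[, ax]) + margin)
    lo:hi
  })
}

crop_to_box <- function(a, box) a[box[[1]], box[[2]], box[[3]], drop = FALSE]

# Separable Gaussian smoothing of a 3D array (reflecting edges), used by the
# phantom generator to build spatially correlated texture fields.
smooth_gaussian3d <- function(a, sigma_vox) {
  sigma_vox <- rep_len(sigma_vox, 3L)
  dm <- dim(a)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 0) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-(seq(-half, half))^2 / (2 * s^2))
    k <- k / sum(k)
    a <- apply_along(a, ax, function(v) conv1d_reflect(v, k))
  }
  a
}

apply_along <- function(a, ax, f) {
  dm <- dim(a)
  perm <- c(ax, setdiff(1:3, ax))
  ap <- aperm(a, perm)
  m <- matrix(ap, nrow = dm[ax])
  m <- apply(m, 2, f)
  ap <- array(m, dim = dm[perm])
  aperm(ap, order(perm))
}

conv1d_reflect <- function(v, k) {
  half <- (length(k) - 1L) / 2L
  n <- length(v)
  # reflecting pad, clamped for short vectors
  pre <- pmin(pmax(rev(seq_len(half)), 1L), n)
  post <- pmin(pmax(n + 1L - seq_len(half), 1L), n)
  vp <- c(v[pre], v, v[post])
  out <- stats::filter(vp, k, sides = 2)
  as.numeric(out[(half + 1L):(half + n)])
}

# Moment skewness m3 / m2^{3/2}; 0 for degenerate input.
moment_skewness <- function(x) {
  n <- length(x)
  if (n < 2L) return(0)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^3) / m2^1.5
}

moment_kurtosis <- function(x) {
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 <= 0) return(0)
  mean((x - m)^4) / m2^2
}

# Shannon entropy (log2) of a probability vector.
entropy_log2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}
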