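# Brute-force reference implementations used as independent oracles for the
# texture extractors, ring construction and AUC. Deliberately naive (triple
# loops, flood fills) and kept structurally unrelated to the package code.

in_grid <- function(v, dm) all(v >= 1L) && all(v <= dm)

valid_at <- function(q, roi, v) {
  roi[v[1], v[2], v[3]] && !is.na(q[v[1], v[2], v[3]])
}

oracle_glcm <- function(q, roi, L, distance = 1L) {
  dm <- dim(q)
  M <- matrix(0, L, L)
  offs <- list()
  for (d in slnradiomics:::DIRECTIONS_13) {
    offs[[length(offs) + 1L]] <- d * distance
    offs[[length(offs) + 1L]] <- -d * distance
  }
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    v <- c(x, y, z)
    if (!valid_at(q, roi, v)) next
    for (d in offs) {
      u <- v + d
      if (!in_grid(u, dm) || !valid_at(q, roi, u)) next
      M[q[x, y, z] + 1L, q[u[1], u[2], u[3]] + 1L] <-
        M[q[x, y, z] + 1L, q[u[1], u[2], u[3]] + 1L] + 1
    }
  }
  if (sum(M) == 0) stop("no pairs")
  M / sum(M)
}

oracle_ngldm <- function(q, roi, L) {
  dm <- dim(q)
  n <- numeric(L)
  s <- numeric(L)
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    v <- c(x, y, z)
    if (!valid_at(q, roi, v)) next
    nb <- c()
    for (d in slnradiomics:::NEIGHBOURS_26) {
      u <- v + d
      if (in_grid(u, dm) && valid_at(q, roi, u))
        nb <- c(nb, q[u[1], u[2], u[3]])
    }
    if (length(nb) == 0L) next
    lv <- q[x, y, z]
    n[lv + 1L] <- n[lv + 1L] + 1
    s[lv + 1L] <- s[lv + 1L] + abs(lv - mean(nb))
  }
  data.frame(level = which(n > 0) - 1L, n = as.integer(n[n > 0]), s = s[n > 0])
}

oracle_glrlm <- function(q, roi, L) {
  dm <- dim(q)
  runs <- list()
  for (d in slnradiomics:::DIRECTIONS_13) {
    for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
      v <- c(x, y, z)
      if (!valid_at(q, roi, v)) next
      prev <- v - d
      lv <- q[x, y, z]
      # run start: predecessor missing or different
      if (in_grid(prev, dm) && valid_at(q, roi, prev) &&
          q[prev[1], prev[2], prev[3]] == lv) next
      len <- 1L
      u <- v + d
      while (in_grid(u, dm) && valid_at(q, roi, u) &&
             q[u[1], u[2], u[3]] == lv) {
        len <- len + 1L
        u <- u + d
      }
      runs[[length(runs) + 1L]] <- c(lv, len)
    }
  }
  rr <- do.call(rbind, runs)
  R <- matrix(0, L, max(rr[, 2]))
  for (i in seq_len(nrow(rr))) R[rr[i, 1] + 1L, rr[i, 2]] <- R[rr[i, 1] + 1L, rr[i, 2]] + 1
  R
}

oracle_glzlm <- function(q, roi, L) {
  dm <- dim(q)
  seen <- array(FALSE, dm)
  zones <- list()
  all_d <- slnradiomics:::NEIGHBOURS_26
  for (x in 1:dm[1]) for (y in 1:dm[2]) for (z in 1:dm[3]) {
    v <- c(x, y, z)
    if (seen[x, y, z] || !valid_at(q, roi, v)) next
    lv <- q[x, y, z]
    stack <- list(v)
    seen[x, y, z] <- TRUE
    size <- 0L
    while (length(stack) > 0L) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      size <- size + 1L
      for (d in all_d) {
        u <- cur + d
        if (in_grid(u, dm) && !seen[u[1], u[2], u[3]] &&
            valid_at(q, roi, u) && q[u[1], u[2], u[3]] == lv) {
          seen[u[1], u[2], u[3]] <- TRUE
          stack[[length(stack) + 1L]] <- u
        }
      }
    }
    zones[[length(zones) + 1L]] <- c(lv, size)
  }
  zz <- do.call(rbind, zones)
  Z <- matrix(0, L, max(zz[, 2]))
  for (i in seq_len(nrow(zz))) Z[zz[i, 1] + 1L, zz[i, 2]] <- Z[zz[i, 1] + 1L, zz[i, 2]] + 1
  Z
}

# direct 5x5 zero-padded 2D correlation
oracle_correlate2d <- function(m, K) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  for (x in 1:nr) for (y in 1:nc) {
    acc <- 0
    for (i in 1:5) for (j in 1:5) {
      xs <- x + i - 3L
      ys <- y + j - 3L
      if (xs >= 1 && xs <= nr && ys >= 1 && ys <= nc)
        acc <- acc + K[i, j] * m[xs, ys]
    }
    out[x, y] <- acc
  }
  out
}

# per-slice brute-force ring membership by scanning every mask voxel
oracle_ring <- function(mask, distance, spacing) {
  dm <- dim(mask)
  ring <- array(FALSE, dm)
  for (z in 1:dm[3]) {
    midx <- which(mask[, , z], arr.ind = TRUE)
    if (nrow(midx) == 0L) next
    for (x in 1:dm[1]) for (y in 1:dm[2]) {
      if (mask[x, y, z]) next
      d2 <- (midx[, 1] - x)^2 * spacing[1]^2 + (midx[, 2] - y)^2 * spacing[2]^2
      if (min(d2) <= distance^2 + 1e-12) ring[x, y, z] <- TRUE
    }
  }
  ring
}

oracle_auc_pairs <- function(scores, labels) {
  y <- as.logical(labels)
  sp <- scores[y]
  sn <- scores[!y]
  tot <- 0
  for (a in sp) for (b in sn) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

# random quantized volume + ROI with guaranteed adjacent in-ROI voxels
random_roi_case <- function(seed, dm = c(5L, 5L, 3L), L = 6L, p_roi = 0.7) {
  withr::with_seed(seed, {
    q <- array(sample(0:(L - 1L), prod(dm), replace = TRUE), dim = dm)
    roi <- array(runif(prod(dm)) < p_roi, dim = dm)
    roi[1:2, 1, 1] <- TRUE              # at least one adjacent pair
    list(q = q, roi = roi, L = L)
  })
}
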