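# Conventional radiomics: shape, first-order, and the four texture-matrix
# families against trivial cases and exhaustive brute-force oracles.

test_that("shape features: cube and digitized ball", {
  dm <- c(8, 8, 8)
  cube <- array(FALSE, dm); cube[3:6, 3:6, 3:6] <- TRUE
  sh <- extract_shape(cube, c(1, 1, 1))
  expect_equal(sh[["shape_extent"]], 1.0)
  expect_equal(sh[["shape_volume_mm3"]], 64)
  expect_equal(sh[["shape_surface_mm2"]], 6 * 16)
  expect_equal(sh[["shape_compacity"]], 1 / sh[["shape_sphericity"]])

  # digitized ball: voxel-counted extent approaches pi/6 as the radius grows
  # (the voxel bounding box spans 2r+1 voxels, so small radii bias downward)
  ball <- slnradiomics:::ellipsoid_mask(c(63, 63, 63), c(1, 1, 1), c(30, 30, 30))
  shb <- extract_shape(ball, c(1, 1, 1))
  expect_lt(abs(shb[["shape_extent"]] - pi / 6) / (pi / 6), 0.05)
  # intensities play no role: identical for any image, and spacing scales volume
  shb2 <- extract_shape(ball, c(0.5, 0.5, 0.5))
  expect_equal(shb2[["shape_volume_mm3"]], shb[["shape_volume_mm3"]] / 8)
  expect_error(extract_shape(array(FALSE, dm), c(1, 1, 1)), "empty")
})

test_that("first-order features match a direct-summation oracle", {
  dm <- c(3, 3, 1)
  roi <- array(TRUE, dm)
  const <- array(5L, dm)
  fo <- extract_first_order(const, roi)
  expect_equal(fo[["fo_variance"]], 0)
  expect_equal(fo[["fo_entropy_log2"]], 0)
  expect_equal(fo[["fo_energy"]], 1)

  two <- array(c(2L, 7L), c(2, 1, 1))
  fo2 <- extract_first_order(two, array(TRUE, c(2, 1, 1)))
  expect_equal(fo2[["fo_entropy_log2"]], 1)  # two equally frequent levels

  withr::with_seed(11, {
    q <- array(sample(0:7, 9, replace = TRUE), dm)
    x <- as.numeric(q)
    fo3 <- extract_first_order(q, roi)
    expect_equal(fo3[["fo_mean"]], mean(x))
    expect_equal(fo3[["fo_variance"]], mean((x - mean(x))^2))
    p <- as.numeric(table(x)) / length(x)
    expect_equal(fo3[["fo_entropy_log2"]], -sum(p * log2(p)))
    expect_equal(fo3[["fo_energy"]], sum(p^2))
    expect_equal(fo3[["fo_skewness"]],
                 mean((x - mean(x))^3) / mean((x - mean(x))^2)^1.5)
    expect_equal(fo3[["fo_kurtosis"]],
                 mean((x - mean(x))^4) / mean((x - mean(x))^2)^2)
  })
  expect_error(extract_first_order(array(1L, c(1, 1, 1)), array(TRUE, c(1, 1, 1))),
               "voxels")
})

test_that("GLCM: trivial cases and brute-force equivalence", {
  dm <- c(2, 1, 1)
  # constant region -> single cell
  cst <- array(3L, c(2, 2, 2))
  f <- extract_glcm(cst, array(TRUE, c(2, 2, 2)), levels = 8)
  expect_equal(f[["glcm_entropy_log2"]], 0)
  expect_equal(f[["glcm_energy"]], 1)
  # 1x1x2 region with levels (0,1): one symmetric pair -> entropy 1 bit
  pair <- array(c(0L, 1L), dm)
  fp <- extract_glcm(pair, array(TRUE, dm), levels = 2)
  expect_equal(fp[["glcm_entropy_log2"]], 1)

  for (seed in 1:6) {
    cs <- random_roi_case(seed, dm = c(4L, 4L, 2L), L = 5L)
    M <- glcm_matrix(cs$q, cs$roi, levels = cs$L)
    expect_equal(M, oracle_glcm(cs$q, cs$roi, cs$L), tolerance = 1e-12)
    expect_equal(sum(M), 1)
    expect_true(all(M >= 0 & M <= 1))
  }
})

test_that("NGLDM: constant region and brute-force equivalence", {
  cst <- array(2L, c(3, 3, 1))
  roi <- array(TRUE, c(3, 3, 1))
  f <- extract_ngldm(cst, roi)
  expect_equal(f[["ngldm_contrast"]], 0)
  expect_equal(f[["ngldm_coarseness"]], 1e6)  # epsilon-guarded maximum

  for (seed in 1:6) {
    cs <- random_roi_case(seed + 100, dm = c(3L, 3L, 3L), L = 4L)
    tb <- ngldm_table(cs$q, cs$roi)
    expect_equal(tb, oracle_ngldm(cs$q, cs$roi, cs$L), tolerance = 1e-12)
  }
})

test_that("GLRLM: single voxel, constant line, brute-force equivalence", {
  dm <- c(3, 3, 3)
  one <- array(FALSE, dm); one[2, 2, 2] <- TRUE
  q <- array(1L, dm)
  f <- extract_glrlm(q, one, levels = 2)
  expect_equal(f[["glrlm_rp"]], 1)       # 13 runs of length 1 over 13 * 1

  line <- array(FALSE, c(1, 1, 4))
  f2 <- glrlm_matrix(array(0L, c(1, 1, 4)), array(TRUE, c(1, 1, 4)), levels = 1)
  expect_equal(f2[1, 4], 1)              # one run of length 4 along the axis

  for (seed in 1:6) {
    cs <- random_roi_case(seed + 200, dm = c(4L, 4L, 1L), L = 4L)
    R <- glrlm_matrix(cs$q, cs$roi, levels = cs$L)
    expect_equal(R, oracle_glrlm(cs$q, cs$roi, cs$L), tolerance = 1e-12)
  }
})

test_that("GLZLM: zones, connectivity and brute-force equivalence", {
  cst <- array(4L, c(3, 2, 1))
  roi <- array(TRUE, c(3, 2, 1))
  f <- extract_glzlm(cst, roi, levels = 8)
  expect_equal(f[["glzlm_zp"]], 1 / 6)   # single zone of 6 voxels

  # two disjoint same-level blobs -> two zones
  q <- array(0L, c(7, 1, 1))
  r2 <- array(TRUE, c(7, 1, 1))
  q[4, 1, 1] <- 1L
  Z <- glzlm_matrix(q, r2, levels = 2)
  expect_equal(Z[1, 3], 2)               # level 0: two zones of size 3
  expect_equal(Z[2, 1], 1)

  for (seed in 1:6) {
    cs <- random_roi_case(seed + 300, dm = c(5L, 5L, 1L), L = 3L)
    Z <- glzlm_matrix(cs$q, cs$roi, levels = cs$L)
    expect_equal(Z, oracle_glzlm(cs$q, cs$roi, cs$L), tolerance = 1e-12)
  }
})

test_that("90-degree in-plane rotation leaves aggregated GLCM/GLRLM unchanged", {
  cs <- random_roi_case(42, dm = c(6L, 6L, 1L), L = 5L)
  rot_q <- array(t(apply(cs$q[, , 1], 2, rev)), c(6, 6, 1))
  rot_roi <- array(t(apply(cs$roi[, , 1], 2, rev)), c(6, 6, 1))
  expect_equal(extract_glcm(cs$q, cs$roi, levels = cs$L),
               extract_glcm(rot_q, rot_roi, levels = cs$L), tolerance = 1e-12)
  expect_equal(extract_glrlm(cs$q, cs$roi, levels = cs$L),
               extract_glrlm(rot_q, rot_roi, levels = cs$L), tolerance = 1e-12)
})
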