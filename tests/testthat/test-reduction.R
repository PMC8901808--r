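# Normalization, ADASYN rebalancing, Mann-Whitney / Spearman / PCA reduction
# and the hyperparameter grid search.

test_that("z-score anchors on training statistics and drops constants", {
  tr <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(0, 10, 20))
  va <- cbind(a = c(2, 4), b = c(5, 6), c = c(10, 30))
  expect_warning(z <- fit_apply_zscore(tr, list(validation = va)), "zero-variance")
  expect_equal(unname(z$train[, "a"]), c(-1, 0, 1))        # n-1 convention
  expect_false("b" %in% colnames(z$train))
  expect_false("b" %in% colnames(z$others$validation))
  expect_equal(unname(z$others$validation[1, "a"]), 0)     # value == training mean
  expect_equal(colMeans(z$train), c(a = 0, c = 0))
  expect_equal(apply(z$train, 2, sd), c(a = 1, c = 1))
})

test_that("ADASYN balances 10/30 and interpolates along minority segments", {
  withr::with_seed(2, {
    x <- rbind(matrix(rnorm(10 * 3, mean = 2), 10, 3),
               matrix(rnorm(30 * 3), 30, 3))
    colnames(x) <- paste0("f", 1:3)
    y <- c(rep(TRUE, 10), rep(FALSE, 30))
  })
  out <- rebalance_adasyn(x, y, seed = 5)
  n_syn <- sum(out$synthetic)
  expect_true(abs(sum(out$y) - sum(!out$y)) <= 3)          # ~30/30
  expect_true(abs(n_syn - 20) <= 3)
  expect_identical(out$x[1:40, ], x)                        # originals unchanged
  expect_true(all(out$y[out$synthetic]))                    # synthetic are minority

  # every synthetic row lies on a segment between a minority sample and one
  # of its minority-class nearest neighbours
  min_x <- x[y, , drop = FALSE]
  for (i in which(out$synthetic)) {
    s <- out$x[i, ]
    on_seg <- FALSE
    for (a in seq_len(nrow(min_x))) for (b in seq_len(nrow(min_x))) {
      if (a == b) next
      u <- min_x[b, ] - min_x[a, ]
      w <- s - min_x[a, ]
      lam <- sum(w * u) / sum(u * u)
      if (lam >= -1e-9 && lam <= 1 + 1e-9 &&
          sqrt(sum((w - lam * u)^2)) < 1e-8) { on_seg <- TRUE; break }
    }
    expect_true(on_seg)
  }

  # already balanced -> zero synthetic rows
  xb <- x[1:20, ]; yb <- rep(c(TRUE, FALSE), each = 10)
  outb <- rebalance_adasyn(xb, yb, seed = 1)
  expect_equal(sum(outb$synthetic), 0)
  expect_error(rebalance_adasyn(x[1:10, ], rep(TRUE, 10), seed = 1), "class")
  expect_error(rebalance_adasyn(x[c(1:3, 11:30), ], y[c(1:3, 11:30)], seed = 1),
               "k\\+1")
})

test_that("Mann-Whitney filter reproduces the exact small-sample p-value", {
  x <- cbind(sep = c(1, 2, 3, 4, 5, 6, 7, 8),
             same = rep(c(1, 2, 3, 4), 2))
  y <- c(TRUE, TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE)
  res <- mannwhitney_filter(x, y, p_threshold = 0.05)
  expect_equal(unname(res$p["sep"]), 2 / 70)               # exact enumeration
  expect_true("sep" %in% res$keep)
  res2 <- mannwhitney_filter(x, y, p_threshold = 0.01)
  expect_false("sep" %in% res2$keep)                        # removed at 0.01
  expect_gt(res$p[["same"]], 0.9)                           # identical groups
  expect_false("same" %in% res$keep)
})

test_that("correlation pruning removes duplicates and respects the threshold", {
  withr::with_seed(3, {
    n <- 50
    x <- cbind(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    x <- cbind(x, dup = x[, "a"])                           # rho = 1 duplicate
    kept <- correlation_prune(x, 0.95)
    expect_equal(sum(c("a", "dup") %in% kept), 1L)          # one of the pair
    # independent noise at n=50, threshold .95: all mutually retained
    expect_true(all(c("b", "c") %in% kept))
    # post-condition by exhaustive pair scan
    rho <- abs(cor(x[, kept], method = "spearman"))
    diag(rho) <- 0
    expect_lt(max(rho), 0.95)
    # priority decides the representative
    kept2 <- correlation_prune(x, 0.95, priority = c(2, 3, 4, 1))
    expect_true("dup" %in% kept2 && !("a" %in% kept2))
  })
})

test_that("PCA is train-anchored with non-increasing component variances", {
  withr::with_seed(4, {
    basis <- matrix(rnorm(6 * 2), 6, 2)
    sc_tr <- matrix(rnorm(40 * 2), 40, 2) %*% t(basis)      # exact 2D subspace
    colnames(sc_tr) <- paste0("f", 1:6)
    sc_va <- matrix(rnorm(10 * 2), 10, 2) %*% t(basis)
    colnames(sc_va) <- paste0("f", 1:6)
    pr <- pca_reduce(sc_tr, list(validation = sc_va), k = 2)
    recon <- pr$train %*% t(pr$basis$rotation)
    recon <- sweep(recon, 2, -pr$basis$center)
    expect_equal(max(abs(recon - sc_tr)), 0, tolerance = 1e-9)

    full <- pca_reduce(sc_tr + matrix(rnorm(240, sd = .01), 40, 6),
                       k = 6)
    v <- apply(full$train, 2, var)
    expect_true(all(diff(v) <= 1e-12))                      # non-increasing
    expect_error(pca_reduce(sc_tr, k = 50), "too large")
  })
})

test_that("grid search returns the representable printed optimum cell and is deterministic", {
  toy <- toy_tables(seed = 10)
  grid <- data.frame(p_threshold = c(0.05, 0.001),
                     rho_threshold = c(0.95, 0.75),
                     pca_components = c(NA, NA))
  g1 <- select_reduction_params(grid, toy$tables, toy$labels, n_seeds = 3,
                                model_config = model_config(n_seeds = 3))
  g2 <- select_reduction_params(grid, toy$tables, toy$labels, n_seeds = 3,
                                model_config = model_config(n_seeds = 3))
  expect_identical(g1$params, g2$params)
  expect_equal(nrow(g1$summary), 2L)
  # the study's printed optima are representable grid cells
  expect_silent(reduction_params(0.05, 0.95, NA))
  expect_error(reduction_params(0.02, 0.95, NA), "grid")
  one <- select_reduction_params(grid[1, ], toy$tables, toy$labels, n_seeds = 2,
                                 model_config = model_config(n_seeds = 2))
  expect_equal(one$params$p_threshold, 0.05)
})

test_that("full reduction keeps splits separated and order-faithful", {
  toy <- toy_tables(seed = 20)
  red <- reduce_features(toy$tables, toy$labels, reduction_params(0.05, 0.95, NA),
                         seed = 3)
  expect_true(red$state$fitted_on_training)
  # planted informative image features survive
  expect_true(any(grepl("feat1$|feat2$", red$state$retained)))
  # clinical columns bypass filtering and are present
  expect_true(all(grepl("^clinical:", colnames(red$train)) |
                    colnames(red$train) %in% c(red$state$retained, paste0("PC", 1:100))))
  expect_true("clinical:age" %in% colnames(red$validation))
  # validation transformed with training stats: reproduce by hand
  mu <- colMeans(toy$tables$train)
  s <- apply(toy$tables$train, 2, sd)
  va_z <- sweep(sweep(toy$tables$validation, 2, mu), 2, s, `/`)
  cols <- colnames(red$validation)
  expect_equal(red$validation[, "clinical:age"], va_z[, "clinical:age"])
})
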