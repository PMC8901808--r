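# Small fixtures built in code: quick phantom studies and cohorts on small
# grids so the default test run stays fast.

quick_config <- function(n_train = 8L, n_val = 5L, n_test = 4L, seed = 1L, ...) {
  phantom_config(n_train = n_train, n_val = n_val, n_test = n_test,
                 grid_shape = c(36L, 36L, 8L), seed = seed, ...)
}

quick_study <- function(seed = 1L, grid = c(36L, 36L, 8L),
                        spacing = c(0.7, 0.7, 2.0),
                        latents = list(baseline = 100, washin = 1.5,
                                       washout = 0.25, heterogeneity = 0.15,
                                       radii_mm = c(6, 6, 4))) {
  make_tumor_phantom(latents, grid, spacing, seed = seed,
                     clinical = quick_clinical(), subject_id = "T001")
}

quick_clinical <- function(lvi = TRUE, grade = 2L) {
  list(upper_inner_quadrant = FALSE, multifocality = FALSE, age = 55,
       pathological_type = "ductal", tumor_grade = grade,
       molecular_subtype = "luminal_a", lymphovascular_invasion = lvi)
}

# deterministic synthetic feature tables for reduction/modeling tests
toy_tables <- function(seed = 1L, n_tr = 60L, n_va = 30L, n_te = 20L, p = 12L,
                       informative = 2L, beta = 2) {
  withr::with_seed(seed, {
    mk <- function(n) {
      y <- runif(n) < 0.35
      x <- matrix(rnorm(n * p), n, p)
      for (j in seq_len(informative)) x[, j] <- x[, j] + beta * y
      colnames(x) <- c(paste0("CR:I:wash_out:feat", seq_len(p - 2)),
                       "clinical:lymphovascular_invasion", "clinical:age")
      list(x = x, y = y)
    }
    tr <- mk(n_tr); va <- mk(n_va); te <- mk(n_te)
    list(tables = list(train = tr$x, validation = va$x, test = te$x),
         labels = list(train = tr$y, validation = va$y, test = te$y))
  })
}
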