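# Train-anchored feature reduction: z-score normalization, ADASYN minority
# oversampling, Mann-Whitney filtering, Spearman correlation pruning and
# optional PCA, with every statistic fitted on the training split only.

#' Reduction hyperparameters
#'
#' Values are restricted to the searched grids: p in
#' \{0.001, 0.005, 0.01, 0.05\}, rho in \{0.75, 0.80, 0.85, 0.90, 0.95\},
#' PCA components in \{none, 20, 40, 60, 80, 100\}.
#'
#' @param p_threshold Mann-Whitney retention threshold.
#' @param rho_threshold Spearman pruning threshold.
#' @param pca_components `NA` for no PCA, else the component count.
#' @return object of class `reduction_params`.
#' @export
reduction_params <- function(p_threshold = 0.05, rho_threshold = 0.95,
                             pca_components = NA) {
  if (!p_threshold %in% c(0.001, 0.005, 0.01, 0.05))
    stop_named("params", "p_threshold outside the searched grid")
  if (!rho_threshold %in% c(0.75, 0.80, 0.85, 0.90, 0.95))
    stop_named("params", "rho_threshold outside the searched grid")
  if (!(is.na(pca_components) || pca_components %in% c(20, 40, 60, 80, 100)))
    stop_named("params", "pca_components outside the searched grid")
  structure(list(p_threshold = p_threshold, rho_threshold = rho_threshold,
                 pca_components = pca_components), class = "reduction_params")
}

#' The full reduction hyperparameter grid
#' @return data.frame enumerating all 120 grid cells.
#' @export
reduction_grid <- function() {
  expand.grid(p_threshold = c(0.001, 0.005, 0.01, 0.05),
              rho_threshold = c(0.75, 0.80, 0.85, 0.90, 0.95),
              pca_components = c(NA, 20, 40, 60, 80, 100))
}

#' Z-score normalization anchored on the training split
#'
#' Columns are centred and scaled by the training mean and standard
#' deviation (n-1 convention); validation/test tables reuse the training
#' statistics exactly. Zero-SD training columns are dropped from every table
#' with a warning.
#'
#' @param train numeric matrix (subjects x features).
#' @param others named list of matrices sharing the columns.
#' @return list with `train`, `others`, `state` (per-feature mean/sd and the
#'   retained column names).
#' @export
fit_apply_zscore <- function(train, others = list()) {
  stopifnot(nrow(train) > 0)
  mu <- colMeans(train)
  s <- apply(train, 2, sd)
  keep <- which(s > 0)
  if (length(keep) < ncol(train))
    warning(sprintf("dropping %d zero-variance training column(s)",
                    ncol(train) - length(keep)), call. = FALSE)
  tr <- sweep(sweep(train[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], `/`)
  oth <- lapply(others, function(tb)
    sweep(sweep(tb[, keep, drop = FALSE], 2, mu[keep]), 2, s[keep], `/`))
  state <- list(mean = mu[keep], sd = s[keep], columns = colnames(train)[keep],
                fitted_on_training = TRUE)
  list(train = tr, others = oth, state = state)
}

#' ADASYN minority oversampling
#'
#' Adaptive synthetic sampling: the generation budget
#' G = (N_majority - N_minority) * beta is allocated across minority samples
#' proportionally to their local difficulty (fraction of majority samples
#' among the k nearest neighbours in the full training set), and each
#' synthetic sample is a uniform interpolation between a minority sample and
#' one of its k nearest minority-class neighbours. Originals are unchanged
#' and only ever the training split is rebalanced.
#'
#' @param x numeric matrix (subjects x features).
#' @param y logical/0-1 labels.
#' @param seed RNG seed.
#' @param k neighbour count (default 5).
#' @param beta balance target fraction (default 1 = full balance).
#' @return list with `x`, `y` (augmented), `synthetic` (logical flag per row).
#' @export
rebalance_adasyn <- function(x, y, seed, k = 5L, beta = 1) {
  y <- as.logical(y)
  if (length(unique(y)) < 2L)
    stop_named("adasyn", "both classes must be present")
  n_pos <- sum(y)
  minority <- if (n_pos <= sum(!y)) TRUE else FALSE
  min_idx <- which(y == minority)
  maj_idx <- which(y != minority)
  if (length(min_idx) < k + 1L)
    stop_named("adasyn", "minority class needs at least k+1 = %d samples", k + 1L)
  G <- round((length(maj_idx) - length(min_idx)) * beta)
  if (G <= 0)
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))

  d_all <- as.matrix(dist(x))
  # difficulty: majority fraction among k NN in the whole set
  r <- vapply(min_idx, function(i) {
    nn <- order(d_all[i, -i])             # indices into x[-i]
    nn_global <- seq_len(nrow(x))[-i][nn[seq_len(k)]]
    mean(y[nn_global] != minority)
  }, numeric(1))
  r_hat <- if (sum(r) > 0) r / sum(r) else rep(1 / length(r), length(r))
  g_i <- round(r_hat * G)

  with_seed(seed, {
    new_rows <- list()
    for (ii in seq_along(min_idx)) {
      gi <- g_i[ii]
      if (gi <= 0) next
      i <- min_idx[ii]
      d_min <- d_all[i, min_idx]
      nn_min <- min_idx[order(d_min)][-1]           # exclude self
      nn_min <- nn_min[seq_len(min(k, length(nn_min)))]
      for (s in seq_len(gi)) {
        j <- nn_min[sample.int(length(nn_min), 1L)]
        lam <- runif(1)
        new_rows[[length(new_rows) + 1L]] <- x[i, ] + lam * (x[j, ] - x[i, ])
      }
    }
    if (length(new_rows) == 0L) {
      list(x = x, y = y, synthetic = rep(FALSE, nrow(x)))
    } else {
      xs <- do.call(rbind, new_rows)
      colnames(xs) <- colnames(x)
      list(x = rbind(x, xs),
           y = c(y, rep(minority, nrow(xs))),
           synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(xs))))
    }
  })
}

#' Mann-Whitney class-difference filter
#'
#' Retains features whose two-sided Mann-Whitney U test between the two
#' label groups has p below the threshold (exact p for small untied samples,
#' normal approximation with tie correction otherwise).
#'
#' @param x numeric matrix.
#' @param y labels.
#' @param p_threshold retention threshold (strict `<`).
#' @return list with `keep` (column names) and `p` (named p-value vector).
#' @export
mannwhitney_filter <- function(x, y, p_threshold = 0.05) {
  y <- as.logical(y)
  stopifnot(sum(y) >= 1, sum(!y) >= 1)
  p <- vapply(seq_len(ncol(x)), function(j) {
    suppressWarnings(wilcox.test(x[y, j], x[!y, j])$p.value)
  }, numeric(1))
  names(p) <- colnames(x)
  keep <- colnames(x)[!is.na(p) & p < p_threshold]
  if (length(keep) == 0L)
    message("mannwhitney_filter: no feature passed the threshold")
  list(keep = keep, p = p)
}

#' Spearman correlation pruning
#'
#' Greedy pass in ascending `priority` order (most class-informative first):
#' a feature is kept iff its absolute Spearman correlation with every
#' already-kept feature is strictly below the threshold, so exactly one
#' representative survives per correlated group.
#'
#' @param x numeric matrix.
#' @param rho_threshold pruning threshold.
#' @param priority numeric vector (lower = keep first), e.g. Mann-Whitney
#'   p-values; defaults to column order.
#' @return character vector of retained column names.
#' @export
correlation_prune <- function(x, rho_threshold = 0.95, priority = NULL) {
  stopifnot(ncol(x) >= 1)
  priority <- priority %||% seq_len(ncol(x))
  ord <- order(priority)
  rho <- suppressWarnings(abs(cor(x, method = "spearman")))
  rho[is.na(rho)] <- 0
  kept <- integer(0)
  for (j in ord) {
    if (length(kept) == 0L || all(rho[j, kept] < rho_threshold))
      kept <- c(kept, j)
  }
  colnames(x)[sort(kept)]
}

#' PCA reduction anchored on the training split
#'
#' @param train numeric matrix.
#' @param others named list of matrices with the same columns.
#' @param k component count; must be `<= min(nrow(train) - 1, ncol(train))`.
#' @return list with `train`, `others` (score matrices, columns `PC1..PCk`)
#'   and `basis` (the training rotation and centre).
#' @export
pca_reduce <- function(train, others = list(), k) {
  k <- as.integer(k)
  if (k > min(nrow(train) - 1L, ncol(train)))
    stop_named("pca", "k = %d too large for %d x %d training table",
               k, nrow(train), ncol(train))
  pc <- prcomp(train, center = TRUE, scale. = FALSE)
  rot <- pc$rotation[, seq_len(k), drop = FALSE]
  proj <- function(tb) {
    sc <- sweep(tb, 2, pc$center) %*% rot
    colnames(sc) <- paste0("PC", seq_len(k))
    sc
  }
  out_tr <- pc$x[, seq_len(k), drop = FALSE]
  colnames(out_tr) <- paste0("PC", seq_len(k))
  list(train = out_tr, others = lapply(others, proj),
       basis = list(rotation = rot, center = pc$center))
}

#' Full reduction of an image-feature table
#'
#' Order: z-score (train-anchored) -> ADASYN rebalancing of the training
#' split -> Mann-Whitney filter -> Spearman pruning (representative = lowest
#' Mann-Whitney p) -> optional PCA. Filter statistics are computed on the
#' rebalanced training set; clinical covariates are z-scored and carried
#' through the rebalancing but bypass the filtering stages and are
#' re-attached afterwards.
#'
#' @param tables list with matrices `train`, `validation`, `test` whose
#'   columns mix image features (`CR:`/`DLB:` prefixes) and clinical features
#'   (`clinical:` prefix).
#' @param labels list with logical vectors `train`, `validation`, `test`.
#' @param params a [reduction_params()].
#' @param seed seed for the rebalancing step.
#' @param filter_on_rebalanced compute Mann-Whitney/Spearman statistics on
#'   the rebalanced training set (default) or on the originals.
#' @return list with `train` (rebalanced, reduced), `train_original`,
#'   `validation`, `test`, `labels_train` (rebalanced), `state`.
#' @export
reduce_features <- function(tables, labels, params, seed = 1L,
                            filter_on_rebalanced = TRUE) {
  stopifnot(inherits(params, "reduction_params"))
  img_cols <- grep("^(CR|DLB):", colnames(tables$train), value = TRUE)
  clin_cols <- grep("^clinical:", colnames(tables$train), value = TRUE)

  z <- fit_apply_zscore(tables$train,
                        list(validation = tables$validation, test = tables$test))
  tr <- z$train
  va <- z$others$validation
  te <- z$others$test
  img_cols <- intersect(img_cols, colnames(tr))
  clin_cols <- intersect(clin_cols, colnames(tr))

  reb <- rebalance_adasyn(tr, labels$train, seed = seed)
  fit_x <- if (filter_on_rebalanced) reb$x else tr
  fit_y <- if (filter_on_rebalanced) reb$y else as.logical(labels$train)

  mw <- mannwhitney_filter(fit_x[, img_cols, drop = FALSE], fit_y,
                           params$p_threshold)
  kept <- mw$keep
  if (length(kept) > 1L) {
    kept <- correlation_prune(fit_x[, kept, drop = FALSE],
                              params$rho_threshold,
                              priority = mw$p[kept])
  }

  pca_basis <- NULL
  if (!is.na(params$pca_components) && length(kept) > 0L) {
    k <- params$pca_components
    pr <- pca_reduce(reb$x[, kept, drop = FALSE],
                     list(train_original = tr[, kept, drop = FALSE],
                          validation = va[, kept, drop = FALSE],
                          test = te[, kept, drop = FALSE]), k = k)
    img_tr <- pr$train
    img_tr0 <- pr$others$train_original
    img_va <- pr$others$validation
    img_te <- pr$others$test
    pca_basis <- pr$basis
  } else {
    img_tr <- reb$x[, kept, drop = FALSE]
    img_tr0 <- tr[, kept, drop = FALSE]
    img_va <- va[, kept, drop = FALSE]
    img_te <- te[, kept, drop = FALSE]
  }

  state <- structure(list(zscore = z$state, retained = kept,
                          pca = pca_basis, params = params,
                          mw_p = mw$p, fitted_on_training = TRUE),
                     class = "reduction_state")
  list(train = cbind(img_tr, reb$x[, clin_cols, drop = FALSE]),
       train_original = cbind(img_tr0, tr[, clin_cols, drop = FALSE]),
       validation = cbind(img_va, va[, clin_cols, drop = FALSE]),
       test = cbind(img_te, te[, clin_cols, drop = FALSE]),
       labels_train = reb$y,
       state = state)
}

#' Grid search for reduction hyperparameters
#'
#' For each grid cell, reduces the features, runs the seeded
#' selection/modeling protocol across `n_seeds` seeds and averages the
#' validation accuracy; returns the argmax cell. Deterministic given the
#' seed list.
#'
#' @param grid data.frame like [reduction_grid()] (possibly a subset).
#' @param tables,labels as in [reduce_features()].
#' @param n_seeds seeds per cell (the study protocol uses 100).
#' @param model_config a [model_config()].
#' @return list with `params` (winning [reduction_params()]), `summary`
#'   (per-cell mean validation accuracy).
#' @export
select_reduction_params <- function(grid, tables, labels, n_seeds = 100L,
                                    model_config = NULL) {
  model_config <- model_config %||% model_config(n_seeds = n_seeds)
  acc <- rep(NA_real_, nrow(grid))
  for (ci in seq_len(nrow(grid))) {
    res <- tryCatch({
      params <- reduction_params(grid$p_threshold[ci], grid$rho_threshold[ci],
                                 grid$pca_components[ci])
      red <- reduce_features(tables, labels, params, seed = 1L)
      vals <- vapply(seq_len(n_seeds), function(s) {
        fit <- fit_one_seed(red, labels, model_config, seed = s)
        fit$validation_accuracy
      }, numeric(1))
      mean(vals)
    }, error = function(e) NA_real_)
    acc[ci] <- res
  }
  if (all(is.na(acc)))
    stop_named("grid-search", "all grid cells failed")
  best <- which.max(acc)
  list(params = reduction_params(grid$p_threshold[best],
                                 grid$rho_threshold[best],
                                 grid$pca_components[best]),
       summary = cbind(grid, mean_validation_accuracy = acc))
}
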