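# LASSO-based feature selection, logistic prediction model, Youden
# thresholding, multi-seed model selection and performance reporting.

#' Modeling protocol configuration
#'
#' @param cv_folds LASSO cross-validation folds (default 3).
#' @param max_features cap on selected features (default 10).
#' @param n_seeds protocol repetitions with reshuffled folds (study: 100).
#' @param nlambda,lambda_min_ratio LASSO path: `nlambda` log-spaced values
#'   down to `lambda_min_ratio * lambda_max`.
#' @return object of class `model_config`.
#' @export
model_config <- function(cv_folds = 3L, max_features = 10L, n_seeds = 100L,
                         nlambda = 100L, lambda_min_ratio = 1e-4) {
  stopifnot(cv_folds >= 2L, max_features >= 1L, n_seeds >= 1L)
  structure(list(cv_folds = as.integer(cv_folds),
                 max_features = as.integer(max_features),
                 n_seeds = as.integer(n_seeds),
                 nlambda = as.integer(nlambda),
                 lambda_min_ratio = lambda_min_ratio),
            class = "model_config")
}

#' LASSO feature selection with the one-standard-error rule
#'
#' L1-penalised logistic path (binomial deviance) with k-fold
#' cross-validation; folds are shuffled by `seed`. The chosen lambda is the
#' largest whose CV error is within one standard error of the minimum; if
#' its active set exceeds `max_features`, larger lambdas along the path are
#' taken until the cap is met. Returns the nonzero-coefficient names
#' (possibly none).
#'
#' @param x numeric matrix (reduced image features + clinical columns).
#' @param y logical/0-1 labels.
#' @param config a [model_config()].
#' @param seed fold-shuffling seed.
#' @return character vector of selected feature names.
#' @export
lasso_select <- function(x, y, config = model_config(), seed = 1L) {
  y <- as.logical(y)
  if (length(unique(y)) < 2L) stop_named("lasso", "degenerate labels")
  foldid <- with_seed(seed, sample(rep_len(seq_len(config$cv_folds), length(y))))
  cvfit <- glmnet::cv.glmnet(x, as.numeric(y), family = "binomial", alpha = 1,
                             foldid = foldid, nlambda = config$nlambda,
                             lambda.min.ratio = config$lambda_min_ratio,
                             standardize = FALSE)
  lam_path <- cvfit$lambda
  li <- match(cvfit$lambda.1se, lam_path)
  nz_at <- function(i) {
    cf <- as.matrix(glmnet::coef.glmnet(cvfit$glmnet.fit, s = lam_path[i]))
    rownames(cf)[cf[, 1] != 0 & rownames(cf) != "(Intercept)"]
  }
  sel <- nz_at(li)
  while (length(sel) > config$max_features && li > 1L) {
    li <- li - 1L                         # path is decreasing in lambda
    sel <- nz_at(li)
  }
  sel
}

#' Unpenalised logistic fit on the selected features
#'
#' Maximum-likelihood logistic regression on the selected columns; an empty
#' selection falls back to the intercept-only model (all scores equal the
#' training prevalence).
#'
#' With complete separation (common on small, strongly-signalled rebalanced
#' training sets) IRLS stops at the iteration cap; the returned scores are
#' still monotone in the linear predictor, which is all the Youden
#' thresholding consumes, so the default policy is to warn and keep the
#' iteration-cap fit. `on_nonconvergence = "error"` enforces the strict
#' contract.
#'
#' @param x numeric matrix.
#' @param y labels.
#' @param selected character vector of column names (possibly empty).
#' @param on_nonconvergence `"warn"` (default), `"error"` or `"silent"`.
#' @return object of class `sln_logistic` with `coefficients`, `selected`,
#'   `converged`.
#' @export
fit_logistic <- function(x, y, selected,
                         on_nonconvergence = c("warn", "error", "silent")) {
  on_nonconvergence <- match.arg(on_nonconvergence)
  y <- as.numeric(as.logical(y))
  ctl <- stats::glm.control(maxit = 100L)
  fit <- suppressWarnings({
    if (length(selected) == 0L) {
      glm(y ~ 1, family = binomial(), control = ctl)
    } else {
      df <- as.data.frame(x[, selected, drop = FALSE], check.names = FALSE)
      df$.y <- y
      glm(.y ~ ., data = df, family = binomial(), control = ctl)
    }
  })
  if (!fit$converged) {
    msg <- sprintf("IRLS did not converge (%d selected features; separation?)",
                   length(selected))
    if (on_nonconvergence == "error") stop_named("logistic", msg)
    if (on_nonconvergence == "warn") warning(msg, call. = FALSE)
  }
  structure(list(coefficients = stats::coef(fit), selected = selected,
                 converged = fit$converged), class = "sln_logistic")
}

#' Predicted probabilities from a fitted logistic model
#' @param model a `sln_logistic`.
#' @param x numeric matrix containing the selected columns.
#' @return numeric scores in (0, 1).
#' @export
score_logistic <- function(model, x) {
  sel <- model$selected
  eta <- rep(model$coefficients[["(Intercept)"]], nrow(x))
  if (length(sel) > 0L) {
    # terms keep the data-frame column order, i.e. the order of `sel`
    b <- model$coefficients[-1]
    b[is.na(b)] <- 0                      # aliased (collinear) columns
    eta <- eta + as.numeric(x[, sel, drop = FALSE] %*% b)
  }
  plogis(eta)
}

#' Youden-optimal decision threshold from training scores
#'
#' Candidate cut-points are the midpoints between adjacent sorted unique
#' scores; the one maximising sensitivity + specificity - 1 (predict
#' positive when score >= threshold) is returned, ties resolved toward the
#' lowest threshold.
#'
#' @param scores numeric scores.
#' @param labels labels (both classes present).
#' @return numeric threshold.
#' @export
youden_threshold <- function(scores, labels) {
  y <- as.logical(labels)
  stopifnot(sum(y) >= 1, sum(!y) >= 1)
  u <- sort(unique(scores))
  if (length(u) < 2L)
    stop_named("youden", "threshold undefined for constant scores")
  cand <- (u[-1] + u[-length(u)]) / 2
  yi <- vapply(cand, function(th) {
    pred <- scores >= th
    sum(pred & y) / sum(y) + sum(!pred & !y) / sum(!y) - 1
  }, numeric(1))
  cand[which.max(yi)]                     # which.max takes the first (lowest)
}

# Rank-based AUC (equivalent to pair counting with 0.5 for ties).
auc_rank <- function(scores, labels) {
  y <- as.logical(labels)
  n1 <- sum(y)
  n0 <- sum(!y)
  if (n1 == 0L || n0 == 0L) stop_named("auc", "AUC undefined for one class")
  r <- rank(scores)
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Performance report at a fixed threshold
#'
#' Confusion counts at `score >= threshold`, trapezoidal/rank AUC, and the
#' derived metrics; YI = sensitivity + specificity - 1 by definition.
#'
#' @param scores numeric scores.
#' @param labels labels (both classes present).
#' @param threshold decision threshold.
#' @return named list: `auc`, `sensitivity`, `specificity`, `ppv`, `npv`,
#'   `accuracy`, `youden`, plus the confusion counts `tp`, `fp`, `tn`, `fn`.
#' @export
evaluate <- function(scores, labels, threshold) {
  y <- as.logical(labels)
  if (sum(y) == 0L || sum(!y) == 0L)
    stop_named("evaluate", "need both classes to evaluate")
  stopifnot(all(is.finite(scores)))
  pred <- scores >= threshold
  tp <- sum(pred & y); fn <- sum(!pred & y)
  tn <- sum(!pred & !y); fp <- sum(pred & !y)
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  list(auc = auc_rank(scores, labels),
       sensitivity = sens,
       specificity = spec,
       ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
       npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
       accuracy = (tp + tn) / length(y),
       youden = sens + spec - 1,
       tp = tp, fp = fp, tn = tn, fn = fn)
}

# One protocol iteration: selection, fit, threshold, split accuracies.
fit_one_seed <- function(red, labels, config, seed) {
  sel <- lasso_select(red$train, red$labels_train, config, seed = seed)
  model <- fit_logistic(red$train, red$labels_train, sel,
                        on_nonconvergence = "silent")
  s_tr <- score_logistic(model, red$train)
  if (length(unique(s_tr)) < 2L) {
    threshold <- 0.5                      # majority-class fallback
  } else {
    threshold <- youden_threshold(s_tr, red$labels_train)
  }
  s_va <- score_logistic(model, red$validation)
  train_acc <- mean((s_tr >= threshold) == as.logical(red$labels_train))
  val_acc <- mean((s_va >= threshold) == as.logical(labels$validation))
  list(seed = seed, selected = sel, model = model, threshold = threshold,
       train_accuracy = train_acc, validation_accuracy = val_acc)
}

#' Multi-seed selection protocol and final report
#'
#' For seeds `1..n_seeds`: reshuffle the CV folds, run LASSO selection,
#' fit the logistic model and fix the Youden threshold on training scores.
#' The seed with the highest training accuracy (computed on the rebalanced
#' training set; ties to the lowest seed) provides the frozen prediction
#' model, which is then evaluated on every split with its frozen threshold.
#'
#' @param red reduced splits from [reduce_features()].
#' @param labels list with logical `train`, `validation`, `test`.
#' @param config a [model_config()].
#' @return object of class `fitted_pipeline`: `selected`, `model`,
#'   `threshold`, `winning_seed`, `reports` (per split incl. the original
#'   training rows) and `seed_trace`.
#' @export
run_seed_protocol <- function(red, labels, config = model_config()) {
  fits <- vector("list", config$n_seeds)
  ok <- logical(config$n_seeds)
  for (s in seq_len(config$n_seeds)) {
    fits[[s]] <- tryCatch(fit_one_seed(red, labels, config, seed = s),
                          error = function(e) e)
    ok[s] <- !inherits(fits[[s]], "error")
  }
  if (!any(ok)) stop_named("protocol", "all seeds failed")
  accs <- vapply(fits[ok], `[[`, numeric(1), "train_accuracy")
  winner <- fits[ok][[which.max(accs)]]   # first max = lowest seed

  reports <- list(
    train = evaluate(score_logistic(winner$model, red$train),
                     red$labels_train, winner$threshold),
    train_original = evaluate(score_logistic(winner$model, red$train_original),
                              labels$train, winner$threshold),
    validation = evaluate(score_logistic(winner$model, red$validation),
                          labels$validation, winner$threshold),
    test = evaluate(score_logistic(winner$model, red$test),
                    labels$test, winner$threshold))
  structure(list(selected = winner$selected, model = winner$model,
                 threshold = winner$threshold, winning_seed = winner$seed,
                 threshold_from_training_only = TRUE,
                 reports = reports,
                 seed_trace = data.frame(
                   seed = vapply(fits[ok], `[[`, numeric(1), "seed"),
                   train_accuracy = accs,
                   validation_accuracy = vapply(fits[ok], `[[`, numeric(1),
                                                "validation_accuracy"),
                   n_selected = vapply(fits[ok], function(f)
                     length(f$selected), numeric(1)))),
            class = "fitted_pipeline")
}
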