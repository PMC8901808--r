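# LASSO selection, logistic fitting, Youden thresholding, evaluation and the
# multi-seed protocol.

test_that("LASSO recovers strong planted predictors under the feature cap", {
  withr::with_seed(1, {
    n <- 200; p <- 20
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- paste0("f", seq_len(p))
    eta <- 2.5 * x[, 1] - 2.5 * x[, 2]
    y <- runif(n) < plogis(eta)
  })
  sel <- lasso_select(x, y, model_config(), seed = 1)
  expect_true(all(c("f1", "f2") %in% sel))
  expect_lte(length(sel), 10L)

  # pure noise -> empty or near-empty selection under the 1-SE rule
  withr::with_seed(2, {
    xn <- matrix(rnorm(100 * 15), 100, 15)
    colnames(xn) <- paste0("g", 1:15)
    yn <- runif(100) < 0.4
  })
  sizes <- vapply(1:5, function(s) length(lasso_select(xn, yn, model_config(),
                                                       seed = s)), numeric(1))
  expect_lte(stats::median(sizes), 2)
  expect_error(lasso_select(x, rep(TRUE, n), model_config(), seed = 1),
               "degenerate")
})

test_that("selection size never exceeds the cap across seeds", {
  withr::with_seed(3, {
    n <- 120; p <- 40
    x <- matrix(rnorm(n * p), n, p)
    colnames(x) <- paste0("f", seq_len(p))
    eta <- rowSums(x[, 1:15]) * 0.8
    y <- runif(n) < plogis(eta)
  })
  for (s in 1:8) expect_lte(length(lasso_select(x, y, model_config(), seed = s)), 10L)
})

test_that("logistic fit matches a brute-force likelihood oracle", {
  x <- matrix(c(-1, 0, 2), 3, 1, dimnames = list(NULL, "f"))
  y <- c(FALSE, FALSE, TRUE)
  fit <- fit_logistic(x, y, "f", on_nonconvergence = "silent")
  nll <- function(b0, b1) {
    p <- plogis(b0 + b1 * x[, 1])
    -sum(ifelse(y, log(p), log(1 - p)))
  }
  # grid-search oracle around the fitted point
  b <- fit$coefficients
  best <- nll(b[1], b[2])
  grid <- expand.grid(b0 = b[1] + seq(-0.5, 0.5, by = 0.05),
                      b1 = b[2] + seq(-0.5, 0.5, by = 0.05))
  vals <- mapply(nll, grid$b0, grid$b1)
  expect_lte(best, min(vals) + 1e-6)

  # intercept-only fallback: scores equal training prevalence
  fit0 <- fit_logistic(x, y, character(0))
  expect_equal(unname(score_logistic(fit0, x)), rep(1 / 3, 3))

  # monotone ordering for a label-aligned feature
  withr::with_seed(4, {
    xl <- matrix(c(rnorm(20, 0, .1), rnorm(20, 1, .1)), 40, 1,
                 dimnames = list(NULL, "s"))
    yl <- rep(c(FALSE, TRUE), each = 20)
  })
  fl <- fit_logistic(xl, yl, "s", on_nonconvergence = "silent")
  sc <- score_logistic(fl, xl)
  # monotone in the feature (saturated probabilities may tie at 0/1)
  expect_true(all(diff(sc[order(xl[, 1])]) >= 0))
})

test_that("Youden threshold equals exhaustive cut-point enumeration", {
  th <- youden_threshold(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1))
  expect_equal(th, 0.5)
  # interleaved labels: best attainable YI is 0 at the lowest candidate
  sc <- c(0.9, 0.8, 0.2, 0.1)
  y <- c(1, 0, 1, 0)
  th2 <- youden_threshold(sc, y)
  yi_at <- function(t) {
    pred <- sc >= t
    sum(pred & y == 1) / 2 + sum(!pred & y == 0) / 2 - 1
  }
  cands <- c(0.15, 0.5, 0.85)
  expect_equal(yi_at(th2), max(vapply(cands, yi_at, numeric(1))))
  expect_equal(th2, cands[which.max(vapply(cands, yi_at, numeric(1)))])

  withr::with_seed(5, {
    s <- round(runif(30), 2)
    yy <- runif(30) < 0.4
  })
  th3 <- youden_threshold(s, yy)
  u <- sort(unique(s))
  cand <- (u[-1] + u[-length(u)]) / 2
  yis <- vapply(cand, function(t) {
    mean(s[yy] >= t) + mean(s[!yy] < t) - 1
  }, numeric(1))
  expect_equal(th3, cand[which.max(yis)])
  expect_error(youden_threshold(rep(0.5, 4), c(0, 0, 1, 1)), "constant")
})

test_that("evaluation metrics match pair counting and the YI identity", {
  withr::with_seed(6, {
    s <- runif(40)
    y <- runif(40) < 0.5
    s[sample(40, 5)] <- 0.5              # force ties
  })
  rep_ <- evaluate(s, y, threshold = 0.5)
  expect_equal(rep_$auc, oracle_auc_pairs(s, y))
  expect_equal(rep_$youden, rep_$sensitivity + rep_$specificity - 1)
  # perfect classifier
  perf <- evaluate(c(0.1, 0.2, 0.9, 0.8), c(0, 0, 1, 1), 0.5)
  expect_equal(perf$auc, 1)
  expect_equal(perf$accuracy, 1)
  expect_equal(perf$youden, 1)
  expect_error(evaluate(s, rep(TRUE, 40), 0.5), "class")
  skip_if_not_installed("pROC")
  expect_equal(rep_$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("seed protocol is deterministic and the winner maximizes training accuracy", {
  toy <- toy_tables(seed = 30)
  red <- reduce_features(toy$tables, toy$labels, reduction_params(0.05, 0.95, NA),
                         seed = 1)
  cfgm <- model_config(n_seeds = 6)
  fit1 <- run_seed_protocol(red, toy$labels, cfgm)
  fit2 <- run_seed_protocol(red, toy$labels, cfgm)
  expect_identical(fit1$selected, fit2$selected)
  expect_identical(fit1$winning_seed, fit2$winning_seed)
  expect_true(all(fit1$seed_trace$train_accuracy <=
                    fit1$reports$train$accuracy + 1e-12))
  expect_true(fit1$threshold_from_training_only)
  # single-seed degenerate protocol
  fit3 <- run_seed_protocol(red, toy$labels, model_config(n_seeds = 1))
  expect_equal(fit3$winning_seed, 1)
  # every report carries the full metric set and the YI identity
  for (r in fit1$reports) {
    expect_true(all(c("auc", "sensitivity", "specificity", "ppv", "npv",
                      "accuracy", "youden") %in% names(r)))
    expect_equal(r$youden, r$sensitivity + r$specificity - 1)
  }
})
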