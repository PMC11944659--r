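# Metrics, cross-validation, family ranking, hyperparameter search and
# final evaluation.

test_that("MAE and RMSE follow their definitions and the Jensen ordering", {
  expect_equal(metric_mae(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(metric_mae(c(1, 2, 3), c(1, 2, 4)), 1 / 3)
  expect_equal(metric_mae(c(0, 0), c(1, -1)), 1)
  expect_equal(metric_rmse(c(1, 2, 3), c(1, 2, 4)), sqrt(1 / 3))
  # constant absolute error: RMSE equals MAE
  expect_equal(metric_rmse(1:5, 1:5 + 2), metric_mae(1:5, 1:5 + 2))
  expect_error(metric_mae(1:3, 1:2), "mismatch")
  # RMSE >= MAE on arbitrary pairs
  set.seed(3)
  for (i in 1:50) {
    y <- rnorm(20); yh <- rnorm(20)
    expect_gte(metric_rmse(y, yh), metric_mae(y, yh))
  }
})

test_that("Spearman correlation handles monotone, mid-rank and degenerate cases", {
  y <- c(2, 4, 6, 8)
  expect_equal(metric_spearman(y, exp(y)), 1)
  expect_equal(metric_spearman(y, -y^3), -1)
  expect_equal(metric_spearman(c(1, 2, 3, 4), c(1, 3, 2, 4)), 0.8)
  expect_warning(res <- metric_spearman(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_true(is.na(res))
})

test_that("family ranking sorts by MAE with RMSE and name tie-breaks", {
  mk <- function(f, mae, rmse) structure(
    list(family = f, mae_mean = mae, rmse_mean = rmse, failed = FALSE),
    class = "cv_result")
  res <- list(mk("A", 0.5, 0.6), mk("B", 0.7, 0.7), mk("C", 0.3, 0.4))
  expect_equal(rank_and_select(res, top_k = 2), c("C", "A"))
  tie <- list(mk("A", 0.5, 0.6), mk("B", 0.5, 0.5))
  expect_equal(rank_and_select(tie, top_k = 2), c("B", "A"))
  seven <- lapply(seq_along(MODEL_FAMILIES), function(i)
    mk(MODEL_FAMILIES[i], 0.1 * i, 0.1 * i))
  expect_length(rank_and_select(seven, top_k = 5), 5L)
  failed <- structure(list(family = "Z", failed = TRUE), class = "cv_result")
  expect_equal(rank_and_select(list(failed, mk("A", 1, 1))), "A")
  expect_error(rank_and_select(list(failed)), "all families failed")
})

test_that("cross-validation learns a noiseless single-descriptor target", {
  # 500 molecules, target a deterministic function of one descriptor
  pool <- fx_pool_1000()
  X <- pool$X[1:500, ]
  y <- 2 * as.numeric(scale(X[, "MW"]))
  names(y) <- rownames(X)
  folds <- make_folds(rownames(X), k = 5, seed = 21)
  cv <- cross_validate("ETR", X, y, folds, seed = 1)
  expect_false(cv$failed)
  expect_lt(cv$mae_mean, 0.05 * sd(y))
  expect_gte(cv$rmse_mean, cv$mae_mean)
})

test_that("on pure-noise targets CV MAE approaches the best-constant bound", {
  X <- fx_features_small()
  set.seed(77)
  y <- rnorm(nrow(X))
  names(y) <- rownames(X)
  folds <- make_folds(rownames(X), k = 5, seed = 22)
  cv <- cross_validate("RFR", X, y, folds, seed = 1)
  bound <- sqrt(2 / pi) * sd(y)   # E|X - mu| for a Gaussian
  expect_lt(abs(cv$mae_mean - bound) / bound, 0.2)
})

test_that("cross-validation is deterministic under fixed seeds", {
  X <- fx_features_small()
  set.seed(5)
  y <- rnorm(nrow(X)); names(y) <- rownames(X)
  folds <- make_folds(rownames(X), k = 3, seed = 23)
  a <- cross_validate("CBR", X, y, folds, seed = 4)
  b <- cross_validate("CBR", X, y, folds, seed = 4)
  expect_identical(a$per_fold_mae, b$per_fold_mae)
  c1 <- cross_validate("ABR", X, y, folds, seed = 4)
  c2 <- cross_validate("ABR", X, y, folds, seed = 4)
  expect_identical(c1$per_fold_mae, c2$per_fold_mae)
})

test_that("hyperparameter search never returns a configuration worse than the incumbent", {
  X <- fx_features_small()
  y <- 1.5 * as.numeric(scale(X[, "TPSA"])) + rnorm(nrow(X), 0, 0.3)
  names(y) <- rownames(X)
  folds <- make_folds(rownames(X), k = 3, seed = 31)
  base <- cross_validate("CBR", X, y, folds, seed = 2)
  out <- optimize_hyperparameters("CBR", X, y, folds, budget_seconds = Inf,
                                  max_trials = 3, incumbent_cv = base, seed = 2)
  expect_lte(out$cv$mae_mean, base$mae_mean)
  # trial-capped replay is exactly reproducible
  out2 <- optimize_hyperparameters("CBR", X, y, folds, budget_seconds = Inf,
                                   max_trials = 3, incumbent_cv = base, seed = 2)
  expect_identical(out$params, out2$params)
  expect_equal(out$cv$mae_mean, out2$cv$mae_mean)
  expect_equal(out$n_trials, 3L)
})

test_that("a mean-only model's holdout MAE equals the closed-form deviation", {
  pool <- fx_pool_1000()
  ids <- pool$mols$mol_id[1:120]
  X <- pool$X[ids, ]
  set.seed(9)
  y <- rnorm(120); names(y) <- ids
  sp <- make_split(ids, X, pool$scaffolds[ids], seed = 2)
  # CBR with zero boosting iterations predicts the training mean exactly
  rep <- finalize_and_evaluate("CBR", list(n_iter = 0), sp, X, y)
  tr_mean <- mean(y[names(sp$assignments)[sp$assignments == "train_val"]])
  hold <- y[names(sp$assignments)[sp$assignments == "holdout_scaffold"]]
  expect_equal(rep$scaffold_holdout$mae, mean(abs(hold - tr_mean)),
               tolerance = 1e-12)
})

test_that("no holdout molecule ever enters a fit call", {
  pool <- fx_pool_1000()
  ids <- pool$mols$mol_id[121:280]
  X <- pool$X[ids, ]
  y <- 2 * as.numeric(scale(X[, "MW"])) + rnorm(length(ids), 0, 0.2)
  names(y) <- ids
  sp <- make_split(ids, X, pool$scaffolds[ids], seed = 3)
  tv <- names(sp$assignments)[sp$assignments == "train_val"]
  folds <- make_folds(tv, k = 3, seed = 4)
  reset_fit_log()
  cv <- cross_validate("XGBR", X, y, folds, seed = 1)
  tuned <- optimize_hyperparameters("XGBR", X, y, folds, budget_seconds = Inf,
                                    max_trials = 1, incumbent_cv = cv, seed = 1)
  rep <- finalize_and_evaluate("XGBR", tuned$params, sp, X, y, cv = tuned$cv)
  holdouts <- names(sp$assignments)[sp$assignments != "train_val"]
  expect_length(intersect(fit_log_ids(), holdouts), 0L)
  expect_gt(length(fit_log_ids()), 0L)
  # and the evaluation report satisfies the metric ordering
  expect_gte(rep$scaffold_holdout$rmse, rep$scaffold_holdout$mae)
  expect_gte(rep$leastsim_holdout$rmse, rep$leastsim_holdout$mae)
})
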