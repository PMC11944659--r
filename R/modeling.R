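# Cross-validated family comparison, hyperparameter optimization,
# final retraining and dual-holdout evaluation.

#' Cross-validate one model family
#'
#' For each fold f, fits on the other folds and scores MAE/RMSE on fold f.
#' All families share the same fold plan so the comparison is paired.
#'
#' @param family one of `MODEL_FAMILIES`.
#' @param X feature matrix covering (at least) the fold-plan molecules.
#' @param y named numeric targets (names = molecule ids).
#' @param folds a `fold_plan` from [make_folds()].
#' @param params optional hyperparameter overrides.
#' @param seed integer seed passed to each fold fit.
#' @return A `cv_result`: list with `family`, `per_fold_mae`, `per_fold_rmse`,
#'   `mae_mean`, `mae_sd`, `rmse_mean`, `rmse_sd`, `failed` (logical),
#'   `params`.
#' @export
cross_validate <- function(family, X, y, folds, params = NULL, seed = 1L) {
  ids <- names(folds$fold_of)
  if (!all(ids %in% rownames(X)) || !all(ids %in% names(y)))
    stopf("cross_validate: fold plan must cover molecules present in X and y")
  maes <- rmses <- numeric(folds$k)
  for (f in seq_len(folds$k)) {
    tr <- ids[folds$fold_of != f]
    va <- ids[folds$fold_of == f]
    res <- tryCatch({
      m <- fit_family(family, X[tr, , drop = FALSE], y[tr],
                      params = params, seed = seed)
      p <- predict(m, X[va, , drop = FALSE])
      c(metric_mae(y[va], p), metric_rmse(y[va], p))
    }, error = function(e) e)
    if (inherits(res, "error")) {
      return(structure(list(family = family, failed = TRUE,
                            error = conditionMessage(res), params = params),
                       class = "cv_result"))
    }
    maes[f] <- res[1]; rmses[f] <- res[2]
  }
  structure(list(family = family, per_fold_mae = maes, per_fold_rmse = rmses,
                 mae_mean = mean(maes), mae_sd = stats::sd(maes),
                 rmse_mean = mean(rmses), rmse_sd = stats::sd(rmses),
                 failed = FALSE, params = params),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  if (isTRUE(x$failed)) {
    cat(sprintf("<cv_result> %s: FAILED (%s)\n", x$family, x$error))
  } else {
    cat(sprintf("<cv_result> %s: MAE %.4f +/- %.4f, RMSE %.4f +/- %.4f\n",
                x$family, x$mae_mean, x$mae_sd, x$rmse_mean, x$rmse_sd))
  }
  invisible(x)
}

#' Rank families and keep the best
#'
#' Ascending by cross-validated mean MAE; ties broken by mean RMSE, then by
#' family name. Failed families are excluded from the ranking.
#'
#' @param results list of `cv_result` objects.
#' @param top_k how many families to keep (default 5).
#' @return Character vector of family names, best first (at most `top_k`).
#' @export
rank_and_select <- function(results, top_k = 5L) {
  ok <- Filter(function(r) !isTRUE(r$failed), results)
  if (!length(ok)) stopf("rank_and_select: all families failed")
  fam <- vapply(ok, `[[`, "", "family")
  mae <- vapply(ok, `[[`, 0.0, "mae_mean")
  rmse <- vapply(ok, `[[`, 0.0, "rmse_mean")
  fam[order(mae, rmse, fam)][seq_len(min(top_k, length(fam)))]
}

#' Seeded random-search hyperparameter optimization
#'
#' Randomized search over the family's documented grid, scored by
#' cross-validated MAE under the shared fold plan. The incumbent (default
#' configuration, or `incumbent_params`) is always evaluated first, so the
#' returned configuration is never worse than the incumbent in CV MAE. The
#' search stops at `max_trials` sampled configurations or when
#' `budget_seconds` of wall clock is exhausted, whichever comes first;
#' trial-capped runs are exactly reproducible under the seed.
#'
#' @inheritParams cross_validate
#' @param budget_seconds wall-clock budget (default 60; `Inf` to rely on the
#'   trial cap alone).
#' @param max_trials cap on sampled configurations (default 20).
#' @param incumbent_params starting configuration (default: family defaults).
#' @param incumbent_cv the incumbent's already-computed `cv_result` under the
#'   same fold plan, if available (avoids re-scoring it).
#' @return List with `family`, `params` (winner), `cv` (its `cv_result`),
#'   `n_trials`, `seed`.
#' @export
optimize_hyperparameters <- function(family, X, y, folds,
                                     budget_seconds = 60, max_trials = 20L,
                                     incumbent_params = NULL,
                                     incumbent_cv = NULL, seed = 1L) {
  if (budget_seconds <= 0) stopf("optimize_hyperparameters: budget must be positive")
  t0 <- Sys.time()
  space <- hpo_space(family)
  best_cv <- incumbent_cv %||%
    cross_validate(family, X, y, folds, params = incumbent_params, seed = seed)
  if (isTRUE(best_cv$failed))
    stopf("optimize_hyperparameters: incumbent fit failed for %s", family)
  best <- incumbent_params
  trials <- 0L
  for (t in seq_len(max_trials)) {
    if (as.numeric(Sys.time() - t0, units = "secs") > budget_seconds) break
    cand <- with_seed(seed * 1000L + t,
                      lapply(space, function(v) v[[sample.int(length(v), 1)]]))
    cv <- cross_validate(family, X, y, folds, params = cand, seed = seed)
    trials <- trials + 1L
    if (!isTRUE(cv$failed) && cv$mae_mean < best_cv$mae_mean) {
      best_cv <- cv
      best <- cand
    }
  }
  if (trials == 0L)
    warnf("optimize_hyperparameters: no trials completed within budget; returning incumbent")
  list(family = family, params = best, cv = best_cv, n_trials = trials,
       seed = as.integer(seed))
}

#' Retrain the winner and evaluate on both holdouts
#'
#' One fit on the full train/validation set, then MAE/RMSE/Spearman on the
#' scaffold-based and least-similar holdouts separately. Holdout targets are
#' never touched before this stage.
#'
#' @param family winning family name.
#' @param params its hyperparameters.
#' @param split a `split_assignment`.
#' @param X feature matrix covering all molecules in the split.
#' @param y named numeric targets.
#' @param cv the winner's `cv_result` (carried into the report).
#' @param seed integer seed.
#' @param property optional property name for the report.
#' @return An `evaluation_report`: list with `property`, `best_family`,
#'   `params`, `cv`, `scaffold_holdout` and `leastsim_holdout` (each
#'   `mae`/`rmse`/`spearman`), and the fitted `model`.
#' @export
finalize_and_evaluate <- function(family, params, split, X, y, cv = NULL,
                                  seed = 1L, property = NA_character_) {
  part <- split$assignments
  tr <- names(part)[part == "train_val"]
  sc <- names(part)[part == "holdout_scaffold"]
  ls <- names(part)[part == "holdout_leastsim"]
  if (!length(sc) || !length(ls)) stopf("finalize_and_evaluate: empty holdout")
  model <- fit_family(family, X[tr, , drop = FALSE], y[tr],
                      params = params, seed = seed)
  score <- function(idx) {
    p <- predict(model, X[idx, , drop = FALSE])
    list(mae = metric_mae(y[idx], p), rmse = metric_rmse(y[idx], p),
         spearman = suppressWarnings(metric_spearman(y[idx], p)))
  }
  structure(list(property = property, best_family = family, params = params,
                 cv = cv, scaffold_holdout = score(sc),
                 leastsim_holdout = score(ls), model = model),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, best family %s\n",
              x$property, x$best_family))
  if (!is.null(x$cv) && !isTRUE(x$cv$failed))
    cat(sprintf("  CV:        MAE %.4f +/- %.4f, RMSE %.4f +/- %.4f\n",
                x$cv$mae_mean, x$cv$mae_sd, x$cv$rmse_mean, x$cv$rmse_sd))
  cat(sprintf("  scaffold:  MAE %.4f, RMSE %.4f, Spearman %s\n",
              x$scaffold_holdout$mae, x$scaffold_holdout$rmse,
              format(x$scaffold_holdout$spearman, digits = 3)))
  cat(sprintf("  least-sim: MAE %.4f, RMSE %.4f, Spearman %s\n",
              x$leastsim_holdout$mae, x$leastsim_holdout$rmse,
              format(x$leastsim_holdout$spearman, digits = 3)))
  invisible(x)
}

# JSON-ready view of an evaluation report (mirrors the summary-table layout:
# CV mean +/- sd, then the two holdouts).
report_to_list <- function(rep) {
  list(property = rep$property, best_family = rep$best_family,
       cv = if (!is.null(rep$cv)) list(mae_mean = rep$cv$mae_mean,
                                       mae_sd = rep$cv$mae_sd,
                                       rmse_mean = rep$cv$rmse_mean,
                                       rmse_sd = rep$cv$rmse_sd),
       scaffold = rep$scaffold_holdout,
       least_similar = rep$leastsim_holdout)
}
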