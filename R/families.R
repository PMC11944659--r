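# The seven regressor families.
#
# SVR, RFR, ETR and XGBR wrap e1071, ranger and xgboost. GBR (classic
# least-squares gradient boosting over rpart trees), ABR (AdaBoost.R2 over
# rpart trees) and CBR (gradient boosting with oblivious/symmetric decision
# tables, the CatBoost tree shape) are implemented here as documented
# learners. Default hyperparameters are package constants, decoupled from
# backend-library defaults.

#' @export
MODEL_FAMILIES <- c("SVR", "RFR", "ETR", "GBR", "XGBR", "CBR", "ABR")

#' Default hyperparameters per model family
#'
#' Documented constants (not backend defaults). Tree counts and depths are
#' sized for datasets of a few thousand molecules with ~200 descriptors.
#'
#' @param family one of `MODEL_FAMILIES`.
#' @return Named list of hyperparameters.
#' @export
default_hyperparameters <- function(family) {
  switch(assert_family(family),
    SVR = list(cost = 10, epsilon = 0.1, gamma = NA),  # NA gamma -> 1/ncol(X)
    RFR = list(num_trees = 250, mtry_frac = 1 / 3, min_node = 5),
    ETR = list(num_trees = 250, mtry_frac = 0.5, min_node = 5),
    GBR = list(n_trees = 100, shrinkage = 0.1, maxdepth = 3, minsplit = 10),
    XGBR = list(nrounds = 200, eta = 0.1, max_depth = 6, subsample = 1,
                colsample = 1, min_child_weight = 1),
    CBR = list(n_iter = 50, depth = 4, learning_rate = 0.15, borders = 6),
    ABR = list(n_estimators = 40, maxdepth = 4, loss = "linear")
  )
}

# Randomized-search spaces for hyperparameter optimization, one discrete
# grid per family.
hpo_space <- function(family) {
  switch(assert_family(family),
    SVR = list(cost = c(1, 3, 10, 30, 100), epsilon = c(0.05, 0.1, 0.2),
               gamma_scale = c(0.3, 1, 3)),
    RFR = list(num_trees = c(300, 500), mtry_frac = c(0.2, 1 / 3, 0.5),
               min_node = c(1, 5, 10)),
    ETR = list(num_trees = c(300, 500), mtry_frac = c(1 / 3, 0.6, 1),
               min_node = c(1, 5, 10)),
    GBR = list(n_trees = c(60, 100, 150), shrinkage = c(0.05, 0.1, 0.2),
               maxdepth = c(2, 3, 4)),
    XGBR = list(nrounds = c(100, 200, 400), eta = c(0.05, 0.1, 0.2),
                max_depth = c(3, 6, 9), subsample = c(0.7, 1),
                colsample = c(0.7, 1), min_child_weight = c(1, 5)),
    CBR = list(n_iter = c(50, 100), depth = c(3, 4, 6),
               learning_rate = c(0.1, 0.15, 0.3), borders = c(6, 10)),
    ABR = list(n_estimators = c(25, 40, 60), maxdepth = c(3, 4, 6))
  )
}

assert_family <- function(family) {
  if (length(family) != 1L || !family %in% MODEL_FAMILIES)
    stopf("unknown model family '%s' (expected one of %s)",
          paste(family, collapse = ","), paste(MODEL_FAMILIES, collapse = ", "))
  family
}

# ---- fit-call tracking (leakage guard) -------------------------------------

.fit_registry <- new.env(parent = emptyenv())
.fit_registry$ids <- character(0)

#' Fit-call audit log
#'
#' Every model fit records the molecule ids it trained on; tests assert that
#' no holdout id ever enters a fit call. `reset_fit_log()` clears the log,
#' `fit_log_ids()` returns the union of all ids seen by any fit since.
#'
#' @export
reset_fit_log <- function() {
  .fit_registry$ids <- character(0)
  invisible(NULL)
}

#' @rdname reset_fit_log
#' @export
fit_log_ids <- function() unique(.fit_registry$ids)

record_fit <- function(ids) {
  if (!is.null(ids)) .fit_registry$ids <- c(.fit_registry$ids, ids)
  invisible(NULL)
}

# ---- fitting ----------------------------------------------------------------

#' Fit one model family
#'
#' @param family one of `MODEL_FAMILIES`.
#' @param X numeric feature matrix (rownames = molecule ids; no `NA`).
#' @param y numeric targets.
#' @param params hyperparameters (defaults from [default_hyperparameters()]).
#' @param seed integer seed for any stochastic component of the learner.
#' @return A `qsar_model` object with a [predict][predict.qsar_model] method.
#' @export
fit_family <- function(family, X, y, params = NULL, seed = 1L) {
  assert_family(family)
  if (nrow(X) != length(y)) stopf("fit_family: X/y size mismatch")
  if (anyNA(X) || anyNA(y)) stopf("fit_family: NA in training data; impute first")
  params <- utils::modifyList(default_hyperparameters(family), params %||% list())
  record_fit(rownames(X))
  fit <- switch(family,
    SVR = fit_svr(X, y, params),
    RFR = fit_ranger(X, y, params, seed, extratrees = FALSE),
    ETR = fit_ranger(X, y, params, seed, extratrees = TRUE),
    GBR = fit_gbr(X, y, params),
    XGBR = fit_xgbr(X, y, params, seed),
    CBR = fit_cbr(X, y, params),
    ABR = fit_abr(X, y, params, seed)
  )
  structure(list(family = family, params = params, seed = as.integer(seed),
                 fit = fit, descriptor_names = colnames(X)),
            class = "qsar_model")
}

#' Predict from a fitted model
#'
#' @param object a `qsar_model`.
#' @param newdata feature matrix with the training descriptor columns.
#' @param ... unused.
#' @return Numeric predictions.
#' @export
predict.qsar_model <- function(object, newdata, ...) {
  X <- newdata[, object$descriptor_names, drop = FALSE]
  if (anyNA(X)) stopf("predict: NA in features; impute first")
  switch(object$family,
    SVR = predict_svr(object$fit, X),
    RFR = stats::predict(object$fit, data = as.data.frame(X),
                         num.threads = 1)$predictions,
    ETR = stats::predict(object$fit, data = as.data.frame(X),
                         num.threads = 1)$predictions,
    GBR = predict_gbr(object$fit, X),
    XGBR = stats::predict(object$fit, xgboost::xgb.DMatrix(X)),
    CBR = predict_cbr(object$fit, X),
    ABR = predict_abr(object$fit, X)
  )
}

# ---- SVR (RBF support vector regression; features standardized inside) -----

fit_svr <- function(X, y, p) {
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  gamma <- if (is.na(p$gamma)) 1 / ncol(X) else p$gamma
  if (!is.null(p$gamma_scale)) gamma <- p$gamma_scale / ncol(X)
  m <- e1071::svm(x = Z, y = y, type = "eps-regression", kernel = "radial",
                  cost = p$cost, epsilon = p$epsilon, gamma = gamma,
                  scale = FALSE)
  list(model = m, std = std)
}

predict_svr <- function(fit, X) {
  as.numeric(stats::predict(fit$model, apply_standardizer(fit$std, X)))
}

# ---- RFR / ETR (ranger) ----------------------------------------------------

fit_ranger <- function(X, y, p, seed, extratrees) {
  mtry <- max(1L, floor(p$mtry_frac * ncol(X)))
  ranger::ranger(x = as.data.frame(X), y = y, num.trees = p$num_trees,
                 mtry = mtry, min.node.size = p$min_node,
                 splitrule = if (extratrees) "extratrees" else "variance",
                 num.random.splits = 1,
                 replace = !extratrees,  # ETR: whole dataset per tree
                 sample.fraction = 1,
                 seed = seed, num.threads = 1, verbose = FALSE)
}

# ---- XGBR (xgboost) --------------------------------------------------------

fit_xgbr <- function(X, y, p, seed) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = list(objective = "reg:squarederror", eta = p$eta,
                  max_depth = p$max_depth, subsample = p$subsample,
                  colsample_bytree = p$colsample,
                  min_child_weight = p$min_child_weight,
                  nthread = 1, seed = seed),
    data = dtrain, nrounds = p$nrounds, verbose = 0)
}

# ---- GBR: least-squares gradient boosting over rpart trees -----------------

rpart_ctl <- function(maxdepth, minsplit) {
  rpart::rpart.control(maxdepth = maxdepth, minsplit = minsplit, cp = 0,
                       xval = 0, maxcompete = 0, maxsurrogate = 0,
                       usesurrogate = 0)
}

fit_gbr <- function(X, y, p) {
  df <- as.data.frame(X)
  f0 <- mean(y)
  f <- rep(f0, length(y))
  trees <- vector("list", p$n_trees)
  ctl <- rpart_ctl(p$maxdepth, p$minsplit)
  for (m in seq_len(p$n_trees)) {
    df$.r <- y - f
    tr <- rpart::rpart(.r ~ ., data = df, method = "anova", control = ctl)
    trees[[m]] <- tr
    f <- f + p$shrinkage * stats::predict(tr, df)
  }
  list(f0 = f0, trees = trees, shrinkage = p$shrinkage)
}

predict_gbr <- function(fit, X) {
  df <- as.data.frame(X)
  f <- rep(fit$f0, nrow(X))
  for (tr in fit$trees) f <- f + fit$shrinkage * stats::predict(tr, df)
  as.numeric(f)
}

# ---- ABR: AdaBoost.R2 over rpart trees -------------------------------------

fit_abr <- function(X, y, p, seed) {
  n <- length(y)
  df0 <- as.data.frame(X)
  df0$.y <- y
  w <- rep(1 / n, n)
  models <- list(); betas <- numeric(0)
  ctl <- rpart_ctl(p$maxdepth, 10)
  for (m in seq_len(p$n_estimators)) {
    idx <- with_seed(seed + m, sample.int(n, n, replace = TRUE, prob = w))
    tr <- rpart::rpart(.y ~ ., data = df0[idx, , drop = FALSE],
                       method = "anova", control = ctl)
    pred <- stats::predict(tr, df0)
    err <- abs(y - pred)
    D <- max(err)
    if (D == 0) {  # perfect learner: keep it with near-total weight, stop
      models <- c(models, list(tr)); betas <- c(betas, 1e-10)
      break
    }
    L <- err / D
    errbar <- sum(w * L)
    if (errbar >= 0.5) {
      if (!length(models)) { models <- list(tr); betas <- 0.999 }
      break
    }
    beta <- errbar / (1 - errbar)
    models <- c(models, list(tr)); betas <- c(betas, beta)
    w <- w * beta^(1 - L)
    w <- w / sum(w)
  }
  list(models = models, log_inv_beta = log(1 / betas))
}

predict_abr <- function(fit, X) {
  df <- as.data.frame(X)
  P <- vapply(fit$models, function(tr) stats::predict(tr, df), numeric(nrow(df)))
  if (is.null(dim(P))) P <- matrix(P, nrow = nrow(df))
  wts <- fit$log_inv_beta
  # weighted median across estimators, per molecule
  apply(P, 1, function(row) {
    o <- order(row)
    cw <- cumsum(wts[o])
    row[o][which(cw >= 0.5 * sum(wts))[1]]
  })
}

# ---- CBR: gradient boosting with oblivious (symmetric) trees ---------------
#
# Each boosting step grows one depth-d decision table: a single
# (feature, threshold) test is chosen per level and applied to every node,
# so a tree is a 2^d-cell table. Split candidates are per-feature quantile
# borders precomputed once on the training set.

fit_cbr <- function(X, y, p) {
  n <- nrow(X)
  probs <- seq_len(p$borders) / (p$borders + 1)
  thr <- apply(X, 2, stats::quantile, probs = probs, names = FALSE)
  if (is.null(dim(thr))) thr <- matrix(thr, nrow = 1)
  cand_feat <- rep(seq_len(ncol(X)), each = nrow(thr))
  cand_thr <- as.numeric(thr)
  keep <- !duplicated(cbind(cand_feat, cand_thr))
  cand_feat <- cand_feat[keep]; cand_thr <- cand_thr[keep]
  B <- matrix(0, n, length(cand_feat))
  for (j in seq_along(cand_feat))
    B[, j] <- as.numeric(X[, cand_feat[j]] <= cand_thr[j])

  f0 <- mean(y)
  f <- rep(f0, n)
  iters <- vector("list", p$n_iter)
  for (m in seq_len(p$n_iter)) {
    r <- y - f
    idx <- rep(0L, n)  # cell index within current level
    feats <- integer(p$depth); cuts <- numeric(p$depth)
    for (lev in seq_len(p$depth)) {
      K <- 2^(lev - 1)
      M <- matrix(0, n, K)
      M[cbind(seq_len(n), idx + 1L)] <- 1
      SL <- crossprod(B, M * r)            # candidates x cells: sum r, left
      NL <- crossprod(B, M)                #                 counts, left
      St <- colSums(M * r); Nt <- colSums(M)
      SR <- -sweep(SL, 2, St, "-")  # St - SL
      NR <- -sweep(NL, 2, Nt, "-")
      gain <- SL^2 / pmax(NL, 1) + SR^2 / pmax(NR, 1)
      g <- rowSums(gain)
      best <- which.max(g)
      feats[lev] <- cand_feat[best]; cuts[lev] <- cand_thr[best]
      idx <- 2L * idx + (1L - as.integer(B[, best]))
    }
    cells <- 2^p$depth
    leaf <- numeric(cells)
    sums <- tapply(r, idx, sum); cnts <- tapply(r, idx, length)
    leaf[as.integer(names(sums)) + 1L] <- unlist(sums) / unlist(cnts)
    leaf <- leaf * p$learning_rate
    f <- f + leaf[idx + 1L]
    iters[[m]] <- list(feats = feats, cuts = cuts, leaf = leaf)
  }
  list(f0 = f0, iters = iters)
}

predict_cbr <- function(fit, X) {
  n <- nrow(X)
  f <- rep(fit$f0, n)
  for (it in fit$iters) {
    idx <- rep(0L, n)
    for (lev in seq_along(it$feats)) {
      cond <- as.integer(X[, it$feats[lev]] <= it$cuts[lev])
      idx <- 2L * idx + (1L - cond)
    }
    f <- f + it$leaf[idx + 1L]
  }
  as.numeric(f)
}
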