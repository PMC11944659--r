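# Regression metrics used throughout the pipeline.

#' Mean absolute error
#'
#' @param y observed values.
#' @param yhat predicted values (same length).
#' @return `(1/n) * sum(|y - yhat|)`.
#' @export
metric_mae <- function(y, yhat) {
  if (length(y) != length(yhat)) stopf("metric_mae: length mismatch")
  if (!length(y)) stopf("metric_mae: empty input")
  mean(abs(y - yhat))
}

#' Root mean squared error
#'
#' Always >= [metric_mae()] on the same inputs (Jensen's inequality), with
#' equality iff the absolute error is constant.
#'
#' @inheritParams metric_mae
#' @return `sqrt((1/n) * sum((y - yhat)^2))`.
#' @export
metric_rmse <- function(y, yhat) {
  if (length(y) != length(yhat)) stopf("metric_rmse: length mismatch")
  if (!length(y)) stopf("metric_rmse: empty input")
  sqrt(mean((y - yhat)^2))
}

#' Spearman rank correlation
#'
#' Rank correlation in [-1, 1], ties handled by mid-ranks. Undefined for a
#' constant vector: returns `NA` with a warning.
#'
#' @inheritParams metric_mae
#' @return Spearman's rho, or `NA` if either vector is constant.
#' @export
metric_spearman <- function(y, yhat) {
  if (length(y) != length(yhat)) stopf("metric_spearman: length mismatch")
  if (length(y) < 3L) stopf("metric_spearman: need n >= 3")
  if (stats::sd(y) == 0 || stats::sd(yhat) == 0) {
    warnf("metric_spearman: constant vector, correlation undefined")
    return(NA_real_)
  }
  stats::cor(y, yhat, method = "spearman")
}
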