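# ATC-class property profiling: completeness matrices, boxplot statistics,
# and Mann-Whitney-annotated distribution comparisons.

#' Significance annotation bins
#'
#' Maps a p value to the conventional star annotation: `ns` for
#' 0.05 < p <= 1, `*` for 0.01 < p <= 0.05, `**` for 0.001 < p <= 0.01,
#' `***` for 0.0001 < p <= 0.001, `****` for p <= 0.0001. The bins are
#' exhaustive and mutually exclusive over (0, 1].
#'
#' @param p numeric vector of p values in (0, 1].
#' @return Character vector of annotations.
#' @export
annotate_p <- function(p) {
  if (any(!is.finite(p) | p <= 0 | p > 1)) stopf("annotate_p: p values must be in (0, 1]")
  cut(p, breaks = c(0, 1e-4, 1e-3, 1e-2, 5e-2, 1),
      labels = c("****", "***", "**", "*", "ns"),
      include.lowest = FALSE, right = TRUE) |> as.character()
}

#' Two-sided Mann-Whitney comparison of two samples
#'
#' Two-sided Mann-Whitney-Wilcoxon rank test. The p value is exact (full
#' null enumeration) when the combined sample size is at most 12 and there
#' are no ties; otherwise the normal approximation with tie and continuity
#' correction is used.
#'
#' @param a,b numeric samples (each non-empty).
#' @return A `distribution_comparison`: list with `u_statistic`, `p_value`,
#'   `annotation`, `n_a`, `n_b`, `exact`.
#' @export
#' @examples
#' mann_whitney(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3, ns
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b)) stopf("mann_whitney: both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0
  exact <- (length(a) + length(b)) <= 12 && !ties
  wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided",
                                            exact = exact, correct = TRUE))
  p <- min(1, wt$p.value)
  structure(list(u_statistic = unname(wt$statistic), p_value = p,
                 annotation = annotate_p(p), n_a = length(a), n_b = length(b),
                 exact = exact),
            class = "distribution_comparison")
}

#' @export
print.distribution_comparison <- function(x, ...) {
  cat(sprintf("<mann-whitney> U = %g, p = %.4g (%s), n = %d vs %d%s\n",
              x$u_statistic, x$p_value, x$annotation, x$n_a, x$n_b,
              if (x$exact) ", exact" else ""))
  invisible(x)
}

#' Boxplot statistics
#'
#' Median, quartiles by linear interpolation between order statistics,
#' whiskers at the most extreme data points within 1.5 interquartile ranges
#' of the quartiles, and the points beyond the whiskers as outliers.
#'
#' @param values numeric vector (n >= 1).
#' @return List with `n`, `median`, `q1`, `q3`, `whisker_low`,
#'   `whisker_high`, `outliers`.
#' @export
#' @examples
#' boxplot_stats(c(1, 2, 3, 4, 100))  # 100 is an outlier
boxplot_stats <- function(values) {
  values <- values[is.finite(values)]
  if (!length(values)) stopf("boxplot_stats: need at least one finite value")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  inside <- values >= lo_fence & values <= hi_fence
  list(n = length(values), median = q[2], q1 = q[1], q3 = q[3],
       whisker_low = min(values[inside]), whisker_high = max(values[inside]),
       outliers = sort(values[!inside]))
}

#' Class-by-property completeness matrix
#'
#' Percentage of each ATC level-1 class's drugs having at least one curated
#' value for each experimentally collected property. A drug assigned to
#' multiple classes counts in every matching class, but only once in the
#' Global aggregates: the Global row is computed over unique drugs, and each
#' class's Global column entry is the mean of its per-property percentages
#' (the fraction of filled (drug, property) cells).
#'
#' @param drugs data.frame of molecule records (needs `mol_id`, `is_drug`,
#'   `atc_codes`); only drug rows are used.
#' @param datasets named list of `property_dataset` objects (see
#'   [curate_measurements()]); matrix columns follow
#'   [experimental_properties()] restricted to the datasets present.
#' @return A data.frame: one row per populated ATC level-1 class plus a
#'   `Global` row; one column per property plus a `Global` column. Cells are
#'   percentages to 2 decimals; classes with no drugs are absent (not 0).
#' @export
completeness <- function(drugs, datasets) {
  drugs <- drugs[drugs$is_drug, , drop = FALSE]
  if (!nrow(drugs)) stopf("completeness: no drugs")
  props <- intersect(experimental_properties(), names(datasets))
  if (!length(props)) stopf("completeness: no experimental property datasets supplied")
  codes <- atc_split(drugs$atc_codes)
  level1 <- lapply(codes, function(v) unique(substr(v, 1, 1)))
  classes <- sort(unique(unlist(level1)))
  classes <- classes[classes %in% ATC_LEVEL1]

  has_value <- sapply(props, function(p) drugs$mol_id %in% names(datasets[[p]]$values))
  if (is.null(dim(has_value))) has_value <- matrix(has_value, nrow = nrow(drugs),
                                                   dimnames = list(NULL, props))
  rows <- lapply(classes, function(cl) {
    member <- vapply(level1, function(v) cl %in% v, TRUE)
    cells <- round(100 * colMeans(has_value[member, , drop = FALSE]), 2)
    c(cells, Global = round(mean(cells), 2))
  })
  glob <- round(100 * colMeans(has_value), 2)
  rows <- c(rows, list(c(glob, Global = round(mean(glob), 2))))
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- c(classes, "Global")
  out
}

#' Per-class distribution profiles with experimental-vs-predicted comparison
#'
#' For every ATC class at the requested level (optionally restricted to the
#' children of `parent_class`), computes boxplot statistics of the
#' experimental and predicted value distributions of the class's drugs and
#' their two-sided Mann-Whitney comparison. Classes with fewer than `min_n`
#' experimental points are reported as insufficient data and not tested.
#' Predicted values are retained for all drugs of the class, including those
#' that also have experimental values (the predicted set has full coverage).
#'
#' @param experimental a `property_dataset` of experimental values (sparse).
#' @param predicted a `property_dataset` of predicted values (full coverage
#'   of the drugs).
#' @param drugs molecule records with `mol_id`, `is_drug`, `atc_codes`.
#' @param level ATC level of the classes to profile (1-5).
#' @param parent_class optional ATC code; only its child classes (codes with
#'   this prefix) at `level` are profiled.
#' @param min_n minimum experimental n to run the comparison (default 5).
#' @return A named list, one entry per class: list with `class`, `n_class`
#'   (drugs in class), `experimental` and `predicted` boxplot statistics (or
#'   `NULL` if no data), `comparison` (a `distribution_comparison`, or the
#'   string `"insufficient data"`).
#' @export
profile_classes <- function(experimental, predicted, drugs, level = 1L,
                            parent_class = NULL, min_n = 5L) {
  stopifnot(inherits(experimental, "property_dataset"),
            inherits(predicted, "property_dataset"))
  drugs <- drugs[drugs$is_drug, , drop = FALSE]
  if (!is.null(parent_class)) {
    pc <- parse_atc(parent_class)
    if (pc$level >= level)
      stopf("profile_classes: parent_class level (%d) must be shallower than level (%d)",
            pc$level, level)
  }
  codes <- atc_split(drugs$atc_codes)
  at_level <- lapply(codes, function(v) unique(atc_truncate(v, level)))
  at_level <- lapply(at_level, function(v) v[nzchar(v)])
  classes <- sort(unique(unlist(at_level)))
  if (!is.null(parent_class))
    classes <- classes[startsWith(classes, parent_class)]
  if (!length(classes)) {
    if (!is.null(parent_class))
      stopf("profile_classes: no classes under parent '%s'", parent_class)
    stopf("profile_classes: no ATC classes present at level %d", level)
  }
  out <- list()
  for (cl in classes) {
    member <- vapply(at_level, function(v) cl %in% v, TRUE)
    ids <- drugs$mol_id[member]
    ev <- experimental$values[names(experimental$values) %in% ids]
    pv <- predicted$values[names(predicted$values) %in% ids]
    cmp <- if (length(ev) >= min_n && length(pv) >= 1L)
      mann_whitney(as.numeric(ev), as.numeric(pv)) else "insufficient data"
    out[[cl]] <- list(class = cl, n_class = length(ids),
                      experimental = if (length(ev)) boxplot_stats(ev),
                      predicted = if (length(pv)) boxplot_stats(pv),
                      comparison = cmp)
  }
  out
}

#' Compare drug vs non-drug distributions of one property
#'
#' Convenience wrapper for the drug/non-drug distribution contrast: splits a
#' curated dataset by the drug flag and runs the two-sided Mann-Whitney
#' comparison with significance annotation.
#'
#' @param dataset a `property_dataset`.
#' @param molecules molecule records with `mol_id` and `is_drug`.
#' @return List with `drug` and `non_drug` boxplot statistics and
#'   `comparison`.
#' @export
compare_drug_nondrug <- function(dataset, molecules) {
  isd <- molecules$is_drug[match(names(dataset$values), molecules$mol_id)]
  a <- as.numeric(dataset$values[isd %in% TRUE])
  b <- as.numeric(dataset$values[isd %in% FALSE])
  list(drug = if (length(a)) boxplot_stats(a),
       non_drug = if (length(b)) boxplot_stats(b),
       comparison = mann_whitney(a, b))
}
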