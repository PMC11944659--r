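# Dataset partitioning: 85% train/validation, 7.5% scaffold-based holdout,
# 7.5% least-similar holdout, plus the 5-fold cross-validation plan.

#' Nearest-neighbor descriptor distances
#'
#' For each molecule, the Euclidean distance (on z-score standardized
#' descriptors) to its closest neighbor in the pool. These distances define
#' the least-similar holdout: molecules far from everything else are the
#' hardest, most out-of-domain test cases.
#'
#' @param X numeric feature matrix (>= 2 rows; no `NA` — impute first).
#' @param standardizer optional pre-fitted standardizer; by default one is
#'   fitted on `X` itself (the full candidate pool).
#' @return Numeric vector of nearest-neighbor distances (>= 0).
#' @export
nn_distance <- function(X, standardizer = NULL) {
  if (nrow(X) < 2L) stopf("nn_distance: need at least 2 molecules")
  if (anyNA(X)) stopf("nn_distance: matrix contains NA; impute first")
  standardizer <- standardizer %||% fit_standardizer(X)
  Z <- apply_standardizer(standardizer, X)
  d <- as.matrix(stats::dist(Z))
  diag(d) <- Inf
  unname(apply(d, 1, min))
}

#' Select the least-similar molecules
#'
#' The `k` molecules with the largest nearest-neighbor distances, computed
#' once on the full candidate pool (a static property of each molecule, not
#' an iterative carving). Ties are broken by stable input order (first
#' occurrence wins).
#'
#' @param X feature matrix.
#' @param k number of molecules to select (0 < k < nrow(X)).
#' @inheritParams nn_distance
#' @return Integer vector of selected row indices.
#' @export
least_similar_select <- function(X, k, standardizer = NULL) {
  if (k <= 0) stopf("least_similar_select: k must be positive")
  if (k >= nrow(X)) stopf("least_similar_select: k must be < number of molecules")
  d <- nn_distance(X, standardizer)
  order(-d, seq_along(d))[seq_len(k)]
}

#' Three-way dataset split
#'
#' Partitions molecules into `train_val` (85%), `holdout_scaffold` (7.5%)
#' and `holdout_leastsim` (7.5%) by default. Stage order: (1) the
#' least-similar fraction is removed from the full pool by nearest-neighbor
#' descriptor distance; (2) the scaffold holdout is assembled from the
#' remainder by greedily accumulating whole Murcko-scaffold groups,
#' largest-first, until the target count is reached or first exceeded (a
#' group that would overshoot by more than half its size is skipped); (3)
#' everything else is train/validation. No scaffold key in the scaffold
#' holdout ever appears in train/validation.
#'
#' Target counts are the fractions rounded to the nearest integer, with the
#' remainder going to `train_val`.
#'
#' @param ids molecule identifiers.
#' @param X feature matrix with rownames `ids` (used for the least-similar
#'   stage).
#' @param scaffolds scaffold keys aligned with `ids` (from
#'   [murcko_scaffold()]).
#' @param fractions numeric triple (train_val, scaffold, least-similar);
#'   must sum to 1.
#' @param seed integer seed recorded in the assignment (the split itself is
#'   deterministic given inputs; the seed seeds any downstream fold plan).
#' @return A `split_assignment`: list with `assignments` (named character
#'   vector id -> partition), `fractions`, `counts`, `seed`,
#'   `scaffold_keys_holdout`.
#' @export
make_split <- function(ids, X, scaffolds,
                       fractions = c(0.85, 0.075, 0.075), seed = 1L) {
  n <- length(ids)
  if (n < 20L) stopf("make_split: need at least 20 molecules, got %d", n)
  if (length(scaffolds) != n || nrow(X) != n)
    stopf("make_split: ids, X and scaffolds must align")
  if (abs(sum(fractions) - 1) > 1e-9) stopf("make_split: fractions must sum to 1")
  tab <- table(scaffolds[nzchar(scaffolds)])
  if (length(tab) && max(tab) > (1 - fractions[3]) * n)
    stopf("make_split: a single scaffold covers >%.1f%% of molecules; scaffold holdout infeasible",
          100 * (1 - fractions[3]))

  n_ls <- round(fractions[3] * n)
  n_sc <- round(fractions[2] * n)
  part <- rep("train_val", n)
  names(part) <- ids

  # stage 1: least-similar holdout from the full pool
  ls_idx <- least_similar_select(X, n_ls)
  part[ls_idx] <- "holdout_leastsim"

  # stage 2: whole scaffold groups from the remainder, greedy largest-first
  rest <- which(part == "train_val")
  groups <- split(rest, scaffolds[rest])
  groups <- groups[nzchar(names(groups))]  # acyclic (empty key) never held out as a group
  first_seen <- vapply(groups, min, 0L)
  ord <- order(-lengths(groups), first_seen)
  # accumulate whole groups largest-first while they fit; a group that would
  # overshoot is skipped in favour of smaller ones. If the target is not hit
  # exactly, close with the smallest overshooting group, provided it does
  # not overshoot by more than half its own size.
  acc <- integer(0)
  overshooters <- integer(0)
  for (g in ord) {
    size <- length(groups[[g]])
    have <- length(acc)
    if (have >= n_sc) break
    if (have + size <= n_sc) acc <- c(acc, groups[[g]])
    else overshooters <- c(overshooters, g)
  }
  if (length(acc) < n_sc && length(overshooters)) {
    sizes <- lengths(groups[overshooters])
    g <- overshooters[order(sizes, first_seen[overshooters])[1]]
    size <- length(groups[[g]])
    if (length(acc) + size - n_sc <= size / 2) acc <- c(acc, groups[[g]])
  }
  if (!length(acc))
    stopf("make_split: scaffold holdout infeasible (no scaffold group fits the %d-molecule target)",
          n_sc)
  part[acc] <- "holdout_scaffold"

  counts <- c(train_val = sum(part == "train_val"),
              holdout_scaffold = sum(part == "holdout_scaffold"),
              holdout_leastsim = sum(part == "holdout_leastsim"))
  structure(list(assignments = part, fractions = fractions, counts = counts,
                 seed = as.integer(seed),
                 scaffold_keys_holdout = unique(scaffolds[part == "holdout_scaffold"])),
            class = "split_assignment")
}

#' @export
print.split_assignment <- function(x, ...) {
  cat("<split_assignment>", paste(sprintf("%s=%d", names(x$counts), x$counts),
                                  collapse = ", "),
      sprintf("(seed %d)\n", x$seed))
  invisible(x)
}

#' Five-fold cross-validation plan
#'
#' Uniform random assignment of the train/validation molecules to `k` folds
#' of size differing by at most one, deterministic under the seed.
#'
#' @param train_val_ids identifiers of the train/validation molecules.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return A `fold_plan`: list with `k`, `fold_of` (named integer vector
#'   id -> fold), `seed`.
#' @export
make_folds <- function(train_val_ids, k = 5L, seed = 1L) {
  n <- length(train_val_ids)
  if (k < 2L) stopf("make_folds: k must be >= 2")
  if (n < k) stopf("make_folds: need at least k molecules")
  fold <- with_seed(seed, sample(rep_len(seq_len(k), n)))
  names(fold) <- train_val_ids
  structure(list(k = as.integer(k), fold_of = fold, seed = as.integer(seed)),
            class = "fold_plan")
}

#' Write a split to disk
#'
#' CSV with columns `mol_id,partition,fold` plus a JSON report with counts,
#' realized fractions, the seed and the scaffold-purity check.
#'
#' @param split a `split_assignment`.
#' @param folds a `fold_plan` over its train/validation set.
#' @param scaffolds named scaffold keys (for the purity check).
#' @param dir output directory.
#' @return Invisibly the file paths.
#' @export
write_split <- function(split, folds, scaffolds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(split$assignments)
  df <- data.frame(mol_id = ids, partition = unname(split$assignments),
                   fold = unname(folds$fold_of[ids]), stringsAsFactors = FALSE)
  f <- file.path(dir, "splits.csv")
  utils::write.csv(df, f, row.names = FALSE)
  purity <- length(intersect(
    scaffolds[ids[split$assignments == "holdout_scaffold"]],
    scaffolds[ids[split$assignments == "train_val"]])) == 0
  rep <- list(counts = as.list(split$counts),
              realized_fractions = as.list(split$counts / length(ids)),
              target_fractions = split$fractions,
              seed = split$seed, k = folds$k,
              scaffold_purity_ok = purity)
  g <- file.path(dir, "split_report.json")
  jsonlite::write_json(rep, g, auto_unbox = TRUE, digits = NA)
  invisible(c(f, g))
}
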