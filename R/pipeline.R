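# End-to-end orchestration: curate -> featurize -> split -> cross-validate
# -> select -> tune -> finalize -> evaluate -> profile.

#' Pipeline run configuration
#'
#' All seeds are explicit (no wall-clock defaults); fractions must sum to 1.
#'
#' @param input path to a raw measurement CSV (ingestion dialect), or `NULL`
#'   if `measurements` is given to [run_pipeline()] directly.
#' @param properties properties to model (default: all present in the input).
#' @param fractions train_val / scaffold / least-similar fractions.
#' @param k number of CV folds.
#' @param seeds named list: `split`, `folds`, `model`, `hpo` (integers).
#' @param hpo_budget_seconds wall-clock HPO budget per family.
#' @param hpo_max_trials trial cap per family (deterministic replay mode).
#' @param top_k number of families tuned after the CV comparison.
#' @param min_class_n minimum experimental points per class for profiling
#'   comparisons.
#' @param already_log whether log-scale inputs arrive already transformed.
#' @return A `run_config` object.
#' @export
run_config <- function(input = NULL, properties = NULL,
                       fractions = c(0.85, 0.075, 0.075), k = 5L,
                       seeds = list(split = 1L, folds = 2L, model = 3L, hpo = 4L),
                       hpo_budget_seconds = 60, hpo_max_trials = 3L,
                       top_k = 5L, min_class_n = 5L, already_log = TRUE) {
  if (abs(sum(fractions) - 1) > 1e-9) stopf("run_config: fractions must sum to 1")
  need <- c("split", "folds", "model", "hpo")
  if (!all(need %in% names(seeds)))
    stopf("run_config: seeds must name %s", paste(need, collapse = ", "))
  structure(list(input = input, properties = properties, fractions = fractions,
                 k = as.integer(k), seeds = lapply(seeds, as.integer),
                 hpo_budget_seconds = hpo_budget_seconds,
                 hpo_max_trials = as.integer(hpo_max_trials),
                 top_k = as.integer(top_k), min_class_n = as.integer(min_class_n),
                 already_log = already_log),
            class = "run_config")
}

#' Run the full modeling pipeline
#'
#' Executes curation, featurization, splitting, the seven-family CV
#' comparison, top-k hyperparameter optimization, final retraining,
#' dual-holdout evaluation, and ATC-class profiling, writing every
#' intermediate artifact plus a manifest into `out_dir`.
#'
#' @param config a [run_config()].
#' @param out_dir run directory (created).
#' @param measurements optional raw measurement data.frame (bypasses
#'   `config$input`).
#' @param families model families to compare (default all seven).
#' @return List with `run_dir`, `curated`, `features`, and per-property
#'   `results` (split, fold plan, CV table, HPO winners, evaluation report,
#'   predicted dataset).
#' @export
run_pipeline <- function(config, out_dir, measurements = NULL,
                         families = MODEL_FAMILIES) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(measurements)) {
    if (is.null(config$input)) stopf("run_pipeline: no input configured")
    if (!file.exists(config$input))
      stopf("run_pipeline: input path does not exist: %s", config$input)
    measurements <- read_measurements(config$input)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage: curation
  curated <- curate_measurements(measurements, already_log = config$already_log)
  write_curated(curated, file.path(out_dir, "curated"))
  properties <- config$properties %||% names(curated$datasets)

  # stage: featurization (one matrix for all molecules, pinned config)
  cfg <- descriptor_config()
  ft <- featurize(curated$molecules$smiles, ids = curated$molecules$mol_id,
                  config = cfg)
  imputer <- fit_imputer(ft$matrix)
  X <- apply_imputer(imputer, ft$matrix)
  utils::write.csv(data.frame(mol_id = rownames(X), X, check.names = FALSE),
                   file.path(out_dir, "features.csv"), row.names = FALSE)
  jsonlite::write_json(list(descriptor_names = cfg$names, version = cfg$version,
                            hash = cfg$hash,
                            imputation_medians = as.list(imputer$medians)),
                       file.path(out_dir, "features_meta.json"),
                       auto_unbox = TRUE, digits = NA)
  scaffolds <- murcko_scaffold(curated$molecules$smiles)
  names(scaffolds) <- curated$molecules$mol_id

  results <- list()
  for (p in properties) {
    ds <- curated$datasets[[p]]
    if (is.null(ds)) stopf("run_pipeline: no curated dataset for %s", p)
    ids <- intersect(names(ds$values), rownames(X))
    y <- ds$values[ids]
    Xp <- X[ids, , drop = FALSE]
    pdir <- file.path(out_dir, p)
    dir.create(pdir, showWarnings = FALSE)

    # stage: split + folds
    split <- make_split(ids, Xp, scaffolds[ids], fractions = config$fractions,
                        seed = config$seeds$split)
    tv <- names(split$assignments)[split$assignments == "train_val"]
    folds <- make_folds(tv, k = config$k, seed = config$seeds$folds)
    write_split(split, folds, scaffolds[ids], pdir)

    # stage: seven-family CV comparison (shared folds)
    cvs <- lapply(families, function(fam)
      cross_validate(fam, Xp, y, folds, seed = config$seeds$model))
    names(cvs) <- families
    cv_tab <- do.call(rbind, lapply(cvs, function(r) {
      data.frame(family = r$family, failed = isTRUE(r$failed),
                 mae_mean = r$mae_mean %||% NA, mae_sd = r$mae_sd %||% NA,
                 rmse_mean = r$rmse_mean %||% NA, rmse_sd = r$rmse_sd %||% NA,
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(cv_tab, file.path(pdir, "cv_comparison.csv"),
                     row.names = FALSE)

    # stage: top-k HPO
    top <- rank_and_select(cvs, top_k = config$top_k)
    tuned <- lapply(top, function(fam)
      optimize_hyperparameters(fam, Xp, y, folds,
                               budget_seconds = config$hpo_budget_seconds,
                               max_trials = config$hpo_max_trials,
                               incumbent_cv = cvs[[fam]],
                               seed = config$seeds$hpo))
    tuned_mae <- vapply(tuned, function(t) t$cv$mae_mean, 0.0)
    winner <- tuned[[which.min(tuned_mae)]]

    # stage: final retraining + dual-holdout evaluation
    report <- finalize_and_evaluate(winner$family, winner$params, split,
                                    Xp, y, cv = winner$cv,
                                    seed = config$seeds$model, property = p)
    jsonlite::write_json(report_to_list(report),
                         file.path(pdir, "report.json"),
                         auto_unbox = TRUE, digits = NA)

    # full-coverage predicted dataset (for profiling)
    pred <- predict(report$model, X)
    predicted <- structure(list(property = p, unit_spec = ds$unit_spec,
                                values = stats::setNames(pred, rownames(X)),
                                n_drugs = NA_integer_,
                                n_non_drugs = NA_integer_),
                           class = "property_dataset")
    results[[p]] <- list(split = split, folds = folds, cv = cvs,
                         cv_table = cv_tab, tuned = tuned, report = report,
                         predicted = predicted)
  }

  # stage: profiling (completeness over all curated experimental datasets)
  prof <- NULL
  if (any(curated$molecules$is_drug) &&
      any(nzchar(curated$molecules$atc_codes))) {
    cm <- completeness(curated$molecules, curated$datasets)
    utils::write.csv(cm, file.path(out_dir, "completeness.csv"))
    prof <- list(completeness = cm)
    for (p in properties) {
      prof[[p]] <- profile_classes(curated$datasets[[p]],
                                   results[[p]]$predicted,
                                   curated$molecules, level = 1L,
                                   min_n = config$min_class_n)
    }
  }

  manifest <- list(
    config = unclass(config)[setdiff(names(unclass(config)), "input")],
    descriptor_hash = cfg$hash,
    n_molecules = nrow(curated$molecules),
    properties = properties,
    checksums = as.list(tools::md5sum(list.files(out_dir, recursive = TRUE,
                                                 full.names = TRUE,
                                                 pattern = "\\.(csv|json)$")))
  )
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  list(run_dir = out_dir, curated = curated, features = X, results = results,
       profiling = prof)
}
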