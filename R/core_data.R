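#' Read a raw measurement table
#'
#' Ingests the pipeline's CSV dialect: header
#' `mol_id,smiles,property,value,qualifier,is_drug,atc_codes`, UTF-8, `.`
#' decimal separator, `atc_codes` semicolon-separated, `qualifier` empty
#' except for pKa rows (`acidic`/`basic`).
#'
#' @param path CSV file path.
#' @return data.frame of raw measurements (one row per measurement).
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stopf("input file not found: %s", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("mol_id", "smiles", "property", "value")
  if (!all(need %in% names(df)))
    stopf("measurement table must have columns %s", paste(need, collapse = ","))
  df$value <- as.numeric(df$value)
  if (!"qualifier" %in% names(df)) df$qualifier <- ""
  df$qualifier[is.na(df$qualifier)] <- ""
  if (!"is_drug" %in% names(df)) df$is_drug <- "0"
  df$is_drug <- df$is_drug %in% c("1", "TRUE", "true", "T")
  if (!"atc_codes" %in% names(df)) df$atc_codes <- ""
  df$atc_codes[is.na(df$atc_codes)] <- ""
  bad <- !df$property %in% property_names()
  if (any(bad))
    stopf("unknown property name(s): %s",
          paste(unique(df$property[bad]), collapse = ", "))
  qbad <- nzchar(df$qualifier) & df$property != "pKa"
  if (any(qbad)) stopf("acid/base qualifiers are only valid for pKa rows")
  df
}

#' Curate pKa measurements for one molecule
#'
#' Of multiple macroscopic pKa measurements only the strongest acidic or
#' basic value is retained: the minimum over acidic measurements (strongest
#' acid) or the maximum over basic ones (strongest base). Molecules carrying
#' both acidic and basic measurements are amphoteric and are excluded from
#' the pKa dataset altogether.
#'
#' @param values numeric pKa values for one molecule.
#' @param qualifiers character vector (`"acidic"`/`"basic"`), same length.
#' @return The curated value, or `NA_real_` for the amphoteric-exclusion
#'   sentinel.
#' @export
#' @examples
#' curate_pka(c(4.2, 9.8), c("acidic", "acidic"))  # 4.2
#' curate_pka(c(4.2, 9.0), c("acidic", "basic"))   # NA (amphoteric)
curate_pka <- function(values, qualifiers) {
  if (!length(values)) stopf("curate_pka: empty measurement list")
  if (length(values) != length(qualifiers))
    stopf("curate_pka: values/qualifiers length mismatch")
  if (!all(qualifiers %in% c("acidic", "basic")))
    stopf("curate_pka: pKa records require an acidic/basic qualifier")
  q <- unique(qualifiers)
  if (length(q) > 1L) return(NA_real_)  # amphoteric -> excluded
  if (q == "acidic") min(values) else max(values)
}

#' Aggregate replicate measurements
#'
#' Replicate values of one (molecule, property) pair collected from
#' heterogeneous sources are collapsed to their median, a robust choice when
#' individual sources may carry transcription or assay outliers.
#'
#' @param values numeric vector of replicate measurements (length >= 1).
#' @return The median.
#' @export
aggregate_replicates <- function(values) {
  if (!length(values)) stopf("aggregate_replicates: empty measurement list")
  stats::median(values)
}

#' Apply a property's unit convention to a native value
#'
#' Log-scale properties (logS, logER, logBB, logVDss, logCL, logHL) are
#' stored as base-10 logarithms of the native quantity; when a value arrives
#' on the native scale (`already_log = FALSE`) it is log10-transformed, and
#' non-positive native values are rejected (`NA` with attribute `reason`).
#' Percent properties (HIA, PPB) are clamped to [0, 100] when at most 110
#' (transcription-error heuristic) and rejected beyond that. Other
#' properties pass through unchanged.
#'
#' @param property property name (see [property_registry()]).
#' @param value numeric vector of values.
#' @param already_log for log-scale properties, whether `value` is already a
#'   base-10 logarithm (the default: input columns named log* normally are).
#' @return Numeric vector of transformed values; rejected entries are `NA`
#'   and clamped/rejected counts are attached as attribute `log` (a list
#'   with `clamped` and `rejected`).
#' @export
#' @examples
#' transform_value("logS", 1, already_log = FALSE)   # 0
#' transform_value("PPB", 104.3)                     # clamped to 100
transform_value <- function(property, value, already_log = TRUE) {
  assert_property(property)
  clamped <- 0L; rejected <- 0L
  out <- as.numeric(value)
  if (is_log_property(property) && !already_log) {
    bad <- !is.na(out) & out <= 0
    rejected <- sum(bad)
    out[bad] <- NA_real_
    out[!is.na(out)] <- log10(out[!is.na(out)])
  } else if (is_percent_property(property)) {
    high <- !is.na(out) & out > 100 & out <= 110
    low <- !is.na(out) & out < 0 & out >= -10
    clamped <- sum(high | low)
    out[high] <- 100
    out[low] <- 0
    bad <- !is.na(out) & (out > 100 | out < 0)
    rejected <- sum(bad)
    out[bad] <- NA_real_
  }
  structure(out, log = list(clamped = clamped, rejected = rejected))
}

#' Curate raw measurements into per-property datasets
#'
#' Full curation: molecules are canonicalized and deduplicated by structure
#' key (the same compound reported under several ids collapses to one
#' record), replicate measurements are aggregated (median), pKa follows the
#' strongest-acid/strongest-base rule with amphoteric exclusion, and unit
#' conventions are applied. The result is one value per molecule per
#' property.
#'
#' @param measurements data.frame from [read_measurements()] (or the same
#'   shape built in code).
#' @param already_log whether log-scale property columns arrive already
#'   log10-transformed (default TRUE).
#' @return List with `molecules` (deduplicated molecule records, keyed by
#'   the representative `mol_id`), `datasets` (named list of
#'   `property_dataset` objects), and `curation_log` (counts: ingested,
#'   parsed, deduplicated, and per-property excluded/clamped/rejected).
#' @export
curate_measurements <- function(measurements, already_log = TRUE) {
  mols <- molecule_records(measurements[, c("mol_id", "smiles",
                                            intersect(c("is_drug", "atc_codes"),
                                                      names(measurements)))])
  rec <- mols$records
  # collapse identical structures: representative = first mol_id in input order
  rep_of <- tapply(seq_len(nrow(rec)), rec$structure_key, function(i) i[[1]])
  canon <- rec[sort(unname(unlist(rep_of))), , drop = FALSE]
  # merge drug flags / ATC codes across duplicates of one structure
  key_rows <- split(seq_len(nrow(rec)), rec$structure_key)
  for (k in names(key_rows)) {
    rows <- key_rows[[k]]
    if (length(rows) > 1L) {
      j <- which(canon$structure_key == k)
      canon$is_drug[j] <- any(rec$is_drug[rows])
      codes <- unique(unlist(strsplit(rec$atc_codes[rows], ";", fixed = TRUE)))
      canon$atc_codes[j] <- paste(codes[nzchar(codes)], collapse = ";")
    }
  }
  id_to_rep <- canon$mol_id[match(rec$structure_key[match(measurements$mol_id, rec$mol_id)],
                                  canon$structure_key)]
  meas <- measurements
  meas$rep_id <- id_to_rep
  meas <- meas[!is.na(meas$rep_id), , drop = FALSE]  # skip unparseable molecules

  datasets <- list()
  log_all <- list(ingested = nrow(measurements),
                  parsed = nrow(meas),
                  skipped_molecules = nrow(mols$skipped),
                  deduplicated = nrow(rec) - nrow(canon))
  for (p in unique(meas$property)) {
    sub <- meas[meas$property == p, , drop = FALSE]
    excluded <- 0L
    if (p == "pKa") {
      vals <- vapply(split(sub, sub$rep_id),
                     function(d) curate_pka(d$value, d$qualifier), 0.0)
      excluded <- sum(is.na(vals))
      vals <- vals[!is.na(vals)]
      plog <- list(clamped = 0L, rejected = 0L)
    } else {
      agg <- vapply(split(sub$value, sub$rep_id), aggregate_replicates, 0.0)
      tv <- transform_value(p, agg, already_log = already_log)
      plog <- attr(tv, "log")
      vals <- as.numeric(tv)
      names(vals) <- names(agg)
      vals <- vals[!is.na(vals)]
    }
    isd <- canon$is_drug[match(names(vals), canon$mol_id)]
    datasets[[p]] <- structure(
      list(property = p,
           unit_spec = property_registry()$unit_spec[match(p, property_names())],
           values = vals,
           n_drugs = sum(isd), n_non_drugs = sum(!isd)),
      class = "property_dataset")
    log_all[[p]] <- list(n = length(vals), excluded_amphoteric = excluded,
                         clamped = plog$clamped, rejected = plog$rejected)
  }
  list(molecules = canon, datasets = datasets, curation_log = log_all)
}

#' @export
print.property_dataset <- function(x, ...) {
  cat(sprintf("<property_dataset> %s (%s): %d molecules (%d drugs, %d non-drugs)\n",
              x$property, x$unit_spec, length(x$values), x$n_drugs, x$n_non_drugs))
  invisible(x)
}

#' Write curated outputs
#'
#' Writes one CSV per curated property (`mol_id,smiles,value`) plus a JSON
#' curation log, mirroring the ingestion contract.
#'
#' @param curated result of [curate_measurements()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_curated <- function(curated, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (p in names(curated$datasets)) {
    ds <- curated$datasets[[p]]
    df <- data.frame(mol_id = names(ds$values),
                     smiles = curated$molecules$smiles[
                       match(names(ds$values), curated$molecules$mol_id)],
                     value = unname(ds$values), stringsAsFactors = FALSE)
    f <- file.path(dir, sprintf("curated_%s.csv", p))
    utils::write.csv(df, f, row.names = FALSE)
    paths <- c(paths, f)
  }
  logf <- file.path(dir, "curation_log.json")
  jsonlite::write_json(curated$curation_log, logf, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, logf))
}
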