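# Deterministic synthetic-data generator.
#
# Molecules are enumerated from a fixed internal library of ring scaffolds
# decorated with small substituents, so every SMILES parses and the Murcko
# scaffold structure of the set is known by construction. Property values
# follow a linear model over named (z-scored) descriptors plus additive ATC
# class effects and Gaussian noise, so model-recovery error floors and
# class-profiling power are known analytically.

# Scaffold templates: "{R1}" is a prefix attachment (valid when empty),
# "({R2})" an in-ring attachment. One template per distinct ring system.
SCAFFOLD_TEMPLATES <- c(
  benzene        = "{R1}c1ccc({R2})cc1",
  pyridine       = "{R1}c1ccc({R2})nc1",
  pyrimidine     = "{R1}c1cnc({R2})nc1",
  pyrazine       = "{R1}c1cnc({R2})cn1",
  naphthalene    = "{R1}c1ccc2cc({R2})ccc2c1",
  quinoline      = "{R1}c1ccc2nc({R2})ccc2c1",
  indole         = "{R1}c1ccc2[nH]c({R2})cc2c1",
  benzofuran     = "{R1}c1ccc2oc({R2})cc2c1",
  benzothiophene = "{R1}c1ccc2sc({R2})cc2c1",
  furan          = "{R1}c1cc({R2})oc1",
  thiophene      = "{R1}c1cc({R2})sc1",
  pyrrole        = "{R1}c1cc({R2})[nH]c1",
  imidazole      = "{R1}c1nc({R2})c[nH]1",
  thiazole       = "{R1}c1nc({R2})cs1",
  oxazole        = "{R1}c1nc({R2})co1",
  cyclohexane    = "{R1}C1CCC({R2})CC1",
  cyclopentane   = "{R1}C1CC({R2})CC1",
  cyclopropane   = "{R1}C1CC1",
  piperidine     = "{R1}N1CCC({R2})CC1",
  piperazine     = "{R1}N1CCN({R2})CC1",
  morpholine     = "{R1}N1CCOCC1",
  oxolane        = "{R1}C1CCOC1",
  cyclohexene    = "{R1}C1CCC=CC1",
  pyridazine     = "{R1}c1ccc({R2})nn1"
)

# Substituents valid both as prefix (attached by their last atom) and inside
# parentheses (attached by their first atom); "" = unsubstituted.
SUBSTITUENTS <- c("", "C", "CC", "CCC", "CCCC", "C(C)C", "CO", "CCO", "OC",
                  "OCC", "N", "NC", "CN", "CCN", "O", "Cl", "F", "Br",
                  "C(=O)O", "CC(=O)O")

# Linkers used to join two ring scaffolds into one framework.
RING_LINKERS <- c("", "C", "CC", "O", "CO")

# A template rendered with both attachment slots empty (a bare ring system),
# usable as a prefix substituent itself.
bare_scaffold <- function(template) {
  s <- sub("{R1}", "", template, fixed = TRUE)
  sub("({R2})", "", s, fixed = TRUE)
}

# Default linear property models: coefficients over z-scored descriptors.
default_property_models <- function(properties) {
  all <- list(
    logS    = list(intercept = -3.0, coefficients = c(AlogP = -1.0, MW = -0.5),
                   noise_sd = 0.5, scale = "log"),
    pKa     = list(intercept = 7.0, coefficients = c(HBD = 1.5, TPSA = -1.0),
                   noise_sd = 1.0, scale = "log"),
    HIA     = list(intercept = 80, coefficients = c(TPSA = -8, AlogP = 5),
                   noise_sd = 10, scale = "percent"),
    logER   = list(intercept = 0.3, coefficients = c(TPSA = 0.4),
                   noise_sd = 0.3, scale = "log"),
    logBB   = list(intercept = 0.0, coefficients = c(TPSA = -0.7, AlogP = 0.4),
                   noise_sd = 0.4, scale = "log"),
    PPB     = list(intercept = 85, coefficients = c(AlogP = 8),
                   noise_sd = 10, scale = "percent"),
    logVDss = list(intercept = 0.0, coefficients = c(AlogP = 0.5, TPSA = -0.3),
                   noise_sd = 0.4, scale = "log"),
    logCL   = list(intercept = 0.8, coefficients = c(ROTB = 0.4),
                   noise_sd = 0.5, scale = "log"),
    logHL   = list(intercept = 0.5, coefficients = c(MW = 0.3),
                   noise_sd = 0.3, scale = "log")
  )
  all[intersect(properties, names(all))]
}

#' Specification for a synthetic dataset
#'
#' Defines the statistical structure of a generated molecule set: scaffold
#' diversity, per-property linear models over named (z-scored) descriptors
#' with Gaussian noise, additive ATC-class effects, replicate and
#' amphoteric rates.
#'
#' @param n_molecules number of molecules (>= 20).
#' @param seed integer master seed; all generation randomness derives from it.
#' @param scaffold_library_size number of distinct ring scaffolds drawn from
#'   the internal template library (each is guaranteed to appear when
#'   `n_molecules >= scaffold_library_size`).
#' @param properties which experimental properties to generate tables for.
#' @param property_models named list overriding the default per-property
#'   models; each entry has `intercept`, `coefficients` (named vector over
#'   descriptor names), `noise_sd` (>= 0) and `scale` (`"log"`/`"percent"`).
#' @param class_effects named list: ATC level-1 letter -> named numeric
#'   vector of additive per-property shifts (applied to members of the
#'   class).
#' @param drug_fraction fraction of molecules flagged as drugs (they receive
#'   ATC codes).
#' @param replicate_rate probability that a measurement row is duplicated
#'   with small jitter.
#' @param amphoteric_rate probability that a molecule's pKa is emitted as an
#'   acidic and a basic row (such molecules must be excluded downstream).
#' @param multi_code_prob probability that a drug carries a second ATC code.
#' @param two_ring_prob probability that a molecule carries a second ring
#'   system joined through a short linker (diversifies the Murcko scaffold
#'   population towards many small groups, as in real drug-like sets).
#' @return A `synthetic_spec` object.
#' @export
synthetic_spec <- function(n_molecules = 500, seed = 1L,
                           scaffold_library_size = 12L,
                           properties = c("logS", "pKa"),
                           property_models = NULL,
                           class_effects = list(),
                           drug_fraction = 0.5,
                           replicate_rate = 0.1,
                           amphoteric_rate = 0.1,
                           multi_code_prob = 0.2,
                           two_ring_prob = 0.4) {
  if (n_molecules < 20) stopf("synthetic_spec: n_molecules must be >= 20")
  if (scaffold_library_size > length(SCAFFOLD_TEMPLATES))
    stopf("synthetic_spec: scaffold_library_size exceeds the internal library (%d)",
          length(SCAFFOLD_TEMPLATES))
  if (scaffold_library_size < 1) stopf("synthetic_spec: need at least one scaffold")
  models <- utils::modifyList(default_property_models(properties),
                              property_models %||% list())
  models <- models[intersect(properties, names(models))]
  if (!setequal(names(models), properties))
    stopf("synthetic_spec: no model for propert%s %s",
          "y(ies)", paste(setdiff(properties, names(models)), collapse = ", "))
  for (p in names(models)) {
    if (models[[p]]$noise_sd < 0) stopf("synthetic_spec: noise_sd must be >= 0")
  }
  bad <- setdiff(names(class_effects), ATC_LEVEL1)
  if (length(bad))
    stopf("synthetic_spec: class_effects keys must be ATC level-1 letters (bad: %s)",
          paste(bad, collapse = ", "))
  structure(list(n_molecules = as.integer(n_molecules), seed = as.integer(seed),
                 scaffold_library_size = as.integer(scaffold_library_size),
                 properties = properties, property_models = models,
                 class_effects = class_effects, drug_fraction = drug_fraction,
                 replicate_rate = replicate_rate,
                 amphoteric_rate = amphoteric_rate,
                 multi_code_prob = multi_code_prob,
                 two_ring_prob = two_ring_prob),
            class = "synthetic_spec")
}

#' Generate synthetic molecules
#'
#' Enumerates SMILES from the internal scaffold library decorated with
#' alkyl/halogen/hydroxy/amine substituents. Every output parses; the first
#' `scaffold_library_size` molecules cycle through the selected scaffolds so
#' all are represented. Deterministic under the spec seed.
#'
#' @param spec a `synthetic_spec`.
#' @return data.frame with `mol_id`, `smiles`, `is_drug`, `atc_codes`
#'   (empty; see [assign_atc()]).
#' @export
generate_molecules <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_molecules
  tpl <- SCAFFOLD_TEMPLATES[seq_len(spec$scaffold_library_size)]
  with_seed(spec$seed, {
    scaf <- c(rep_len(seq_along(tpl), min(n, length(tpl))),
              if (n > length(tpl)) sample.int(length(tpl), n - length(tpl),
                                              replace = TRUE))
    r1 <- sample(SUBSTITUENTS, n, replace = TRUE)
    r2 <- sample(SUBSTITUENTS, n, replace = TRUE)
    # a second ring system (joined through a short linker) diversifies the
    # Murcko framework population: frameworks = rings + linkers, so each
    # (ring A, ring B, linker) combination is its own scaffold group. The
    # first scaffold_library_size molecules stay single-ring so every
    # library scaffold is represented.
    second <- stats::runif(n) < spec$two_ring_prob &
      seq_len(n) > length(tpl)
    ring2 <- sample.int(length(tpl), n, replace = TRUE)
    linker <- sample(RING_LINKERS, n, replace = TRUE)
    is_drug <- stats::runif(n) < spec$drug_fraction
    smiles <- vapply(seq_len(n), function(i) {
      s <- tpl[[scaf[i]]]
      pre <- if (second[i]) paste0(bare_scaffold(tpl[[ring2[i]]]), linker[i])
             else r1[i]
      s <- sub("{R1}", pre, s, fixed = TRUE)
      s <- sub("({R2})", if (nzchar(r2[i])) paste0("(", r2[i], ")") else "",
               s, fixed = TRUE)
      s
    }, "")
    data.frame(mol_id = sprintf("SYN%05d", seq_len(n)), smiles = smiles,
               is_drug = is_drug, atc_codes = "", stringsAsFactors = FALSE)
  })
}

#' Assign synthetic ATC codes
#'
#' Drugs receive one (or, with probability `multi_code_prob`, two) ATC codes
#' drawn at levels 1-3 (e.g. `"N"`, `"N05"`, `"N05A"`), with level-1 letters
#' drawn from the `class_effects` keys (falling back to a default letter set
#' when no class effects are specified). Class membership then drives the
#' additive shifts in [generate_property_table()]. Deterministic under the
#' spec seed.
#'
#' @param molecules data.frame from [generate_molecules()].
#' @param spec the `synthetic_spec`.
#' @return `molecules` with `atc_codes` filled for drugs.
#' @export
assign_atc <- function(molecules, spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  letters1 <- names(spec$class_effects)
  if (!length(letters1)) letters1 <- c("N", "C", "J", "A")
  with_seed(spec$seed + 1L, {
    for (i in which(molecules$is_drug)) {
      n_codes <- 1L + (stats::runif(1) < spec$multi_code_prob)
      lt <- sample(letters1, min(n_codes, length(letters1)))
      codes <- vapply(lt, function(l) {
        depth <- sample(1:3, 1)
        code <- l
        if (depth >= 2) code <- paste0(code, sprintf("%02d", sample(1:9, 1)))
        if (depth >= 3) code <- paste0(code, sample(LETTERS[1:5], 1))
        code
      }, "")
      molecules$atc_codes[i] <- paste(codes, collapse = ";")
    }
    molecules
  })
}

#' Generate raw property measurement tables
#'
#' Values follow `y = intercept + sum(w * z(descriptor)) + class_effect +
#' N(0, noise_sd)` per property, where `z()` is the z-score over the
#' generated pool. Percent-scale outputs are clamped to [0, 100]. Replicate
#' rows are injected at `replicate_rate` with small jitter. pKa rows carry
#' an acidic or basic qualifier; at `amphoteric_rate` a molecule gets both
#' (to be excluded by curation). Deterministic under the spec seed.
#'
#' @param molecules data.frame with `mol_id`, `smiles`, `is_drug`,
#'   `atc_codes`.
#' @param spec the `synthetic_spec`.
#' @param features optional precomputed feature matrix (rownames =
#'   `mol_id`); computed with the default descriptor config if omitted.
#' @return data.frame of raw measurements in the ingestion dialect:
#'   `mol_id`, `smiles`, `property`, `value`, `qualifier`, `is_drug`,
#'   `atc_codes`.
#' @export
generate_property_table <- function(molecules, spec, features = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  if (is.null(features)) {
    ft <- featurize(molecules$smiles, ids = molecules$mol_id)
    features <- ft$matrix
  }
  features <- apply_imputer(fit_imputer(features), features)
  Z <- apply_standardizer(fit_standardizer(features), features)
  mols <- molecules[match(rownames(Z), molecules$mol_id), , drop = FALSE]
  n <- nrow(mols)
  letters1 <- lapply(atc_split(mols$atc_codes),
                     function(v) unique(substr(v, 1, 1)))
  rows <- list()
  for (p in names(spec$property_models)) {
    pm <- spec$property_models[[p]]
    unknown <- setdiff(names(pm$coefficients), colnames(Z))
    if (length(unknown))
      stopf("generate_property_table: unknown descriptor(s) in %s model: %s",
            p, paste(unknown, collapse = ", "))
    signal <- as.numeric(Z[, names(pm$coefficients), drop = FALSE] %*%
                           pm$coefficients)
    shift <- vapply(letters1, function(ls) {
      sum(vapply(ls, function(l) {
        eff <- spec$class_effects[[l]]
        if (is.null(eff) || is.na(eff[p] %||% NA)) 0 else unname(eff[p])
      }, 0.0))
    }, 0.0)
    y <- with_seed(spec$seed + 100L + match(p, property_names()),
                   pm$intercept + signal + shift + stats::rnorm(n, 0, pm$noise_sd))
    if (identical(pm$scale, "percent")) y <- pmin(100, pmax(0, y))
    if (p == "pKa") {
      qual <- with_seed(spec$seed + 200L,
                        sample(c("acidic", "basic"), n, replace = TRUE))
      amph <- with_seed(spec$seed + 201L,
                        stats::runif(n) < spec$amphoteric_rate)
      rows[[p]] <- data.frame(mol_id = mols$mol_id, smiles = mols$smiles,
                              property = p, value = y, qualifier = qual,
                              is_drug = mols$is_drug,
                              atc_codes = mols$atc_codes,
                              stringsAsFactors = FALSE)
      if (any(amph)) {
        extra <- rows[[p]][amph, , drop = FALSE]
        extra$qualifier <- ifelse(extra$qualifier == "acidic", "basic", "acidic")
        extra$value <- extra$value +
          ifelse(extra$qualifier == "basic", 2.5, -2.5)
        rows[[paste0(p, "_amph")]] <- extra
      }
    } else {
      rows[[p]] <- data.frame(mol_id = mols$mol_id, smiles = mols$smiles,
                              property = p, value = y, qualifier = "",
                              is_drug = mols$is_drug,
                              atc_codes = mols$atc_codes,
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (spec$replicate_rate > 0) {
    dup <- with_seed(spec$seed + 300L, stats::runif(nrow(out)) < spec$replicate_rate)
    if (any(dup)) {
      extra <- out[dup, , drop = FALSE]
      jit <- with_seed(spec$seed + 301L,
                       stats::rnorm(nrow(extra), 0, 0.02 * pmax(abs(extra$value), 1)))
      extra$value <- extra$value + jit
      out <- rbind(out, extra)
    }
  }
  rownames(out) <- NULL
  out
}

#' Simulate a complete raw dataset
#'
#' Convenience wrapper: generates molecules, assigns ATC codes, generates
#' property tables, and optionally writes the ingestion CSV.
#'
#' @param spec a `synthetic_spec`.
#' @param path optional CSV output path.
#' @return List with `molecules`, `measurements`, and `features` (the
#'   descriptor matrix used for generation).
#' @export
simulate_dataset <- function(spec, path = NULL) {
  mols <- generate_molecules(spec)
  mols <- assign_atc(mols, spec)
  ft <- featurize(mols$smiles, ids = mols$mol_id)
  meas <- generate_property_table(mols, spec, features = ft$matrix)
  if (!is.null(path)) utils::write.csv(meas, path, row.names = FALSE)
  list(molecules = mols, measurements = meas, features = ft$matrix)
}
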