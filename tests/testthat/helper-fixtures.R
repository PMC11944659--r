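# Shared fixtures, built once per test run and memoized. Everything is
# generated in code (no stored data); sizes are kept small except where a
# check is inherently about scale.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# 80-molecule simulated dataset with two properties and class structure.
fx_sim_small <- function() fixture("sim_small", function() {
  spec <- synthetic_spec(
    n_molecules = 80, seed = 101, scaffold_library_size = 10,
    properties = c("logS", "pKa"),
    class_effects = list(N = c(logS = 2), C = c(logS = 0)),
    amphoteric_rate = 0.15)
  list(spec = spec, sim = simulate_dataset(spec))
})

# Imputed feature matrix for the small pool.
fx_features_small <- function() fixture("features_small", function() {
  ft <- fx_sim_small()$sim$features
  apply_imputer(fit_imputer(ft), ft)
})

# 1000-molecule pool with features and scaffolds (split-scale checks).
fx_pool_1000 <- function() fixture("pool_1000", function() {
  spec <- synthetic_spec(n_molecules = 1000, seed = 401,
                         scaffold_library_size = 24, properties = "logS",
                         replicate_rate = 0, amphoteric_rate = 0)
  mols <- generate_molecules(spec)
  ft <- featurize(mols$smiles, ids = mols$mol_id)
  X <- apply_imputer(fit_imputer(ft$matrix), ft$matrix)
  scaff <- murcko_scaffold(mols$smiles)
  names(scaff) <- mols$mol_id
  list(mols = mols, X = X, scaffolds = scaff)
})

# Parameter-recovery study: 2000 molecules, the default logS generative
# model (linear in z-scored descriptors, Gaussian noise sd 0.5), full
# seven-family pipeline with trial-capped tuning. Built once; shared by the
# recovery and metric-identity checks.
fx_recovery_pipeline <- function() fixture("recovery_pipeline", function() {
  spec <- synthetic_spec(n_molecules = 2000, seed = 501,
                         scaffold_library_size = 24, properties = "logS",
                         replicate_rate = 0, amphoteric_rate = 0)
  sim <- simulate_dataset(spec)
  cfg <- run_config(properties = "logS", hpo_max_trials = 1, top_k = 5,
                    hpo_budget_seconds = Inf)
  dir <- file.path(tempdir(), "qsarpipe-recovery-run")
  reset_fit_log()
  res <- run_pipeline(cfg, dir, measurements = sim$measurements)
  list(spec = spec, sim = sim, res = res,
       fit_ids = fit_log_ids(),
       noise_sd = spec$property_models$logS$noise_sd)
})

# Brute-force nearest-neighbor distance oracle (O(n^2), standardized).
oracle_nn_distance <- function(X, standardizer = NULL) {
  standardizer <- standardizer %||% fit_standardizer(X)
  Z <- apply_standardizer(standardizer, X)
  n <- nrow(Z)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i == j) next
      d <- sqrt(sum((Z[i, ] - Z[j, ])^2))
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Full-enumeration two-sided Mann-Whitney p value (tie-free inputs): the
# exact null distribution of U over all choose(n_a + n_b, n_a) labelings.
oracle_mw_exact_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  u_of <- function(x, y) {
    sum(vapply(x, function(v) sum(v > y), 0.0))
  }
  obs <- u_of(a, b)
  m <- min(obs, length(a) * length(b) - obs)
  combos <- utils::combn(n, na)
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  us_m <- pmin(us, length(a) * length(b) - us)
  mean(us_m <= m)
}
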