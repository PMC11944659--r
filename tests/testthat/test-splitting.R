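# Murcko scaffolds, nearest-neighbor distances, least-similar selection,
# the three-way split and the fold plan.

identity_std <- structure(list(mean = 0, sd = 1), class = "qsar_standardizer")

test_that("Murcko scaffolds strip side chains and map acyclic molecules to the empty key", {
  keys <- murcko_scaffold(c("Cc1ccccc1", "c1ccccc1", "CCC",
                            "CCc1ccc(O)cc1", "Cc1ccc(CC)cc1"))
  expect_equal(keys[1], keys[2])   # toluene == benzene framework
  expect_equal(keys[1], keys[4])   # para-substituted variants too
  expect_equal(keys[4], keys[5])
  expect_equal(keys[3], "")        # propane: no rings, empty scaffold
  # ring systems joined by a linker are one framework, distinct from benzene
  bip <- murcko_scaffold(c("c1ccc(Cc2ccccc2)cc1", "Cc1ccc(Cc2ccccc2)cc1"))
  expect_equal(bip[1], bip[2])
  expect_false(bip[1] == keys[1])
})

test_that("nearest-neighbor distances match the line example and the brute-force oracle", {
  X <- matrix(c(0, 1, 2, 10), ncol = 1, dimnames = list(NULL, "x"))
  expect_equal(nn_distance(X, identity_std), c(1, 1, 1, 8))
  expect_equal(nn_distance(matrix(rep(3, 5), ncol = 1), identity_std),
               rep(0, 5))
  expect_error(nn_distance(X[1, , drop = FALSE]), "at least 2")
  set.seed(7)
  M <- matrix(rnorm(500), nrow = 50)
  expect_equal(nn_distance(M), oracle_nn_distance(M), tolerance = 1e-12)
})

test_that("least-similar selection takes the largest-distance molecules with stable ties", {
  X <- matrix(c(0, 1, 2, 10), ncol = 1)
  expect_equal(least_similar_select(X, 1, identity_std), 4L)
  # distances are {1,1,1,8}: after the clear maximum, the tie at 1 resolves
  # by input order
  expect_equal(least_similar_select(X, 2, identity_std), c(4L, 1L))
  same <- matrix(rep(2, 6), ncol = 1)
  expect_equal(least_similar_select(same, 2, identity_std), c(1L, 2L))
  expect_error(least_similar_select(X, 0), "positive")
  expect_error(least_similar_select(X, 4), "< number")
})

test_that("least-similar selection equals the brute-force oracle on random instances", {
  set.seed(11)
  for (rep in 1:25) {
    n <- sample(10:200, 1)
    p <- sample(2:8, 1)
    M <- matrix(rnorm(n * p), nrow = n)
    k <- sample.int(n - 1, 1)
    d <- oracle_nn_distance(M)
    expected <- order(-d, seq_along(d))[seq_len(k)]
    expect_equal(least_similar_select(M, k), expected)
  }
})

test_that("the split realizes the 85/7.5/7.5 rounding rule", {
  pool <- fx_pool_1000()
  sub <- pool$mols$mol_id[1:40]
  sp <- make_split(sub, pool$X[sub, ], pool$scaffolds[sub], seed = 3)
  expect_equal(unname(sp$counts["holdout_leastsim"]), 3L)  # round(0.075*40)
  expect_equal(sum(sp$counts), 40L)
  expect_error(make_split(pool$mols$mol_id[1:10], pool$X[1:10, ],
                          pool$scaffolds[1:10]), "at least 20")
})

test_that("a dataset dominated by one scaffold cannot be scaffold-split", {
  sm <- paste0(c("", "C", "CC", "CCC", "CCCC", "CCCCC", "OC", "NC", "OCC",
                 "CO", "ClC", "O", "N", "CN", "CCN", "CCCN", "NCC", "OCCC",
                 "CCO", "CCCO", "C(C)C", "CC(C)C", "Cl", "F", "Br"),
               "c1ccccc1")
  ft <- featurize(sm)
  X <- apply_imputer(fit_imputer(ft$matrix), ft$matrix)
  sc <- murcko_scaffold(sm)
  expect_error(make_split(rownames(X), X, sc), "infeasible")
})

test_that("split partitions are disjoint, exhaustive and scaffold-pure", {
  pool <- fx_pool_1000()
  set.seed(13)
  for (rep in 1:5) {
    ids <- sample(pool$mols$mol_id, sample(60:200, 1))
    sp <- make_split(ids, pool$X[ids, ], pool$scaffolds[ids], seed = rep)
    expect_setequal(names(sp$assignments), ids)
    expect_equal(sum(sp$counts), length(ids))
    sc_hold <- pool$scaffolds[names(sp$assignments)[sp$assignments == "holdout_scaffold"]]
    sc_train <- pool$scaffolds[names(sp$assignments)[sp$assignments == "train_val"]]
    expect_length(intersect(sc_hold, sc_train), 0L)
  }
})

test_that("fold plans are balanced and deterministic", {
  ids <- sprintf("m%03d", 1:100)
  fp <- make_folds(ids, k = 5, seed = 9)
  expect_equal(unname(table(fp$fold_of)), rep(20L, 5), ignore_attr = TRUE)
  fp2 <- make_folds(sprintf("m%03d", 1:103), k = 5, seed = 9)
  expect_equal(sort(unname(table(fp2$fold_of))), c(20L, 20L, 21L, 21L, 21L),
               ignore_attr = TRUE)
  expect_identical(make_folds(ids, 5, 42)$fold_of, make_folds(ids, 5, 42)$fold_of)
  expect_error(make_folds(ids, k = 1), "k must be")
  expect_error(make_folds(ids[1:3], k = 5), "at least k")
})

test_that("split files and reports round-trip", {
  pool <- fx_pool_1000()
  ids <- pool$mols$mol_id[1:60]
  sp <- make_split(ids, pool$X[ids, ], pool$scaffolds[ids], seed = 5)
  fp <- make_folds(names(sp$assignments)[sp$assignments == "train_val"],
                   k = 5, seed = 6)
  dir <- withr::local_tempdir()
  write_split(sp, fp, pool$scaffolds[ids], dir)
  df <- read.csv(file.path(dir, "splits.csv"))
  expect_setequal(df$mol_id, ids)
  repj <- jsonlite::read_json(file.path(dir, "split_report.json"))
  expect_true(repj$scaffold_purity_ok)
  expect_equal(repj$counts$train_val, unname(sp$counts["train_val"]))
})
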