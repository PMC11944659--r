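# Descriptor vectors and the calculated physicochemical profile.

test_that("the default descriptor configuration has 207 ordered names", {
  cfg <- descriptor_config()
  expect_length(cfg$names, 207L)
  expect_false(anyDuplicated(cfg$names) > 0)
  # the hash pins the order: a reordered config hashes differently
  cfg2 <- descriptor_config(names = rev(cfg$names))
  expect_false(identical(cfg$hash, cfg2$hash))
  # overriding the set is allowed and changes D
  cfg3 <- descriptor_config(names = c("MW", "TPSA", "HBD"))
  expect_length(cfg3$names, 3L)
  expect_error(descriptor_config(names = "noSuchDescriptor"), "unknown")
})

test_that("featurization is deterministic and order-invariant", {
  sm <- c("CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O", "CN1CCCC1")
  f1 <- featurize(sm, ids = paste0("m", 1:4))
  f2 <- featurize(sm, ids = paste0("m", 1:4))
  expect_identical(f1$matrix, f2$matrix)
  expect_equal(dim(f1$matrix), c(4L, 207L))
  # permuting the input order never changes a molecule's vector
  f3 <- featurize(rev(sm), ids = paste0("m", 4:1))
  expect_equal(f1$matrix["m2", ], f3$matrix["m2", ])
  expect_identical(attr(f1$matrix, "descriptor_hash"),
                   attr(f3$matrix, "descriptor_hash"))
})

test_that("physchem matches definitional oracles on a hand-checked panel", {
  # independent oracle: molecular weight as the sum of standard atomic
  # masses for each molecule's known formula
  masses <- c(C = 12.011, H = 1.008, N = 14.007, O = 15.999, Cl = 35.45)
  panel <- list(
    list(smiles = "CCO", formula = c(C = 2, H = 6, O = 1)),            # ethanol
    list(smiles = "c1ccccc1", formula = c(C = 6, H = 6)),              # benzene
    list(smiles = "CC(=O)Oc1ccccc1C(=O)O", formula = c(C = 9, H = 8, O = 4)),
    list(smiles = "Cc1ccccc1", formula = c(C = 7, H = 8)),             # toluene
    list(smiles = "Oc1ccccc1", formula = c(C = 6, H = 6, O = 1)),      # phenol
    list(smiles = "Nc1ccccc1", formula = c(C = 6, H = 7, N = 1)),      # aniline
    list(smiles = "CC(=O)O", formula = c(C = 2, H = 4, O = 2)),        # acetic acid
    list(smiles = "c1ccncc1", formula = c(C = 5, H = 5, N = 1)),       # pyridine
    list(smiles = "C1CCCCC1", formula = c(C = 6, H = 12)),             # cyclohexane
    list(smiles = "Clc1ccccc1", formula = c(C = 6, H = 5, Cl = 1))     # chlorobenzene
  )
  pc <- physchem(vapply(panel, `[[`, "", "smiles"))
  for (i in seq_along(panel)) {
    expected_mw <- sum(masses[names(panel[[i]]$formula)] * panel[[i]]$formula)
    expect_equal(pc$MW[i], expected_mw, tolerance = 0.01)
  }
  # benzene: no polar atoms, no acyclic bonds
  benz <- pc[pc$mol_id == pc$mol_id[2], ]
  expect_equal(benz[, c("PSA", "HBA", "HBD", "ROTB")],
               data.frame(PSA = 0, HBA = 0, HBD = 0, ROTB = 0, row.names = 2L))
  # ethanol: one OH donor, one O acceptor, zero rotatable bonds
  # (the C-O bond is terminal at oxygen by heavy-atom degree)
  expect_equal(pc$HBD[1], 1)
  expect_equal(pc$HBA[1], 1)
  # aspirin: three single acyclic non-terminal bonds rotate
  expect_equal(pc$ROTB[3], 3)
})

test_that("imputation freezes training medians and fills NA cells", {
  X <- matrix(c(1, 2, 3, NA, 10, 20, NA, 40), ncol = 2,
              dimnames = list(paste0("m", 1:4), c("a", "b")))
  imp <- fit_imputer(X)
  expect_equal(unname(imp$medians), c(2, 20))
  filled <- apply_imputer(imp, X)
  expect_equal(unname(filled[4, "a"]), 2)
  expect_equal(unname(filled[3, "b"]), 20)
  # prediction-time data uses the frozen training medians, not its own
  Xnew <- matrix(c(100, NA), ncol = 2, dimnames = list("z", c("a", "b")))
  expect_equal(unname(apply_imputer(imp, Xnew)["z", "b"]), 20)
})

test_that("the standardizer z-scores with frozen statistics", {
  X <- matrix(rnorm(60, mean = 5, sd = 3), ncol = 3)
  colnames(X) <- c("a", "b", "c")
  std <- fit_standardizer(X)
  Z <- apply_standardizer(std, X)
  expect_equal(unname(colMeans(Z)), rep(0, 3), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), rep(1, 3), tolerance = 1e-12)
  # zero-variance columns standardize to zero rather than dividing by zero
  Xc <- cbind(X, d = 7)
  Zc <- apply_standardizer(fit_standardizer(Xc), Xc)
  expect_true(all(Zc[, "d"] == 0))
})

test_that("molecules with excessive missing descriptors are excluded with reasons", {
  sm <- c("CCO", "c1ccccc1")
  ft <- featurize(sm, max_na_frac = 0.2)
  expect_equal(nrow(ft$excluded), 0L)
  # force the exclusion path with an impossible threshold
  ft2 <- featurize(sm, max_na_frac = -1)
  expect_equal(nrow(ft2$excluded), 2L)
  expect_match(ft2$excluded$reason[1], "non-finite")
})
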