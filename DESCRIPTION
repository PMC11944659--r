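Package: qsarpipe
Title: Build, Validate and Profile Regression Models of Physicochemical and
    ADME Properties of Small Molecules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantitative structure-property
    modeling of drug-like small molecules. Raw per-property measurement
    tables (SMILES plus values) are curated into one value per unique
    structure, molecules are featurized into a fixed, versioned vector of
    1D/2D descriptors, and datasets are partitioned into a train/validation
    pool plus two harder holdout sets (Murcko-scaffold based and
    least-similar by nearest-neighbor descriptor distance). Seven regressor
    families are compared under shared five-fold cross-validation, the top
    five are tuned by seeded random search, and the winner is retrained and
    evaluated on both holdouts with MAE, RMSE and Spearman rank correlation.
    Downstream profiling tools summarise property distributions across ATC
    drug classes: class-by-property data-completeness matrices, boxplot
    statistics, and Mann-Whitney significance annotation of
    drug-versus-non-drug and experimental-versus-predicted comparisons,
    with drill-down into deeper ATC levels. A deterministic synthetic-data
    generator with known statistical structure supports testing of every
    stage without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineR,
    ChemmineOB,
    e1071,
    ranger,
    xgboost,
    rpart,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
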