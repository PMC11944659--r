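---
title: "Property modeling and ATC-class profiling with qsarpipe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Property modeling and ATC-class profiling with qsarpipe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qsarpipe)
```

## The problem

Absorption, distribution, metabolism and excretion (ADME) behaviour of a
small molecule is governed to a large extent by a modest set of
physicochemical and pharmacokinetic properties: aqueous solubility (logS),
the acid-base dissociation constant (pKa), human intestinal absorption
(HIA), efflux ratio (logER), blood-brain partitioning (logBB), plasma
protein binding (PPB), steady-state volume of distribution (logVDss), total
clearance (logCL) and half-life (logHL), alongside structure-derived
quantities (molecular weight, polar surface area, hydrogen-bond counts,
rotatable bonds, AlogP). Experimental values are sparse and scattered across
heterogeneous sources; regression models trained on curated data provide
full-coverage predictions, which can then be profiled across therapeutic
drug classes of the WHO ATC hierarchy.

qsarpipe implements that workflow end to end: curation of raw measurement
tables, descriptor featurization, dataset partitioning with two
deliberately hard holdout sets, a seven-family model competition under
shared five-fold cross-validation, tuning and final evaluation, and
statistically annotated class profiling. A deterministic synthetic-data
generator with known structure makes every stage testable offline.

## Curation rules

Raw tables carry one row per measurement (`mol_id`, SMILES, property,
value, acid/base qualifier for pKa, drug flag, semicolon-separated ATC
codes). Curation proceeds as follows.

* **Canonicalization and deduplication.** SMILES are canonicalized with
  OpenBabel; the canonical SMILES doubles as the structure key, so the same
  compound reported under several identifiers collapses into one record
  (drug flags are OR-ed, ATC codes unioned). Unparseable SMILES are logged
  and skipped, never fatal.
* **Replicates.** Measurements of one (structure, property) pair are
  collapsed to their **median** — a deliberate design choice: the median is
  robust against the occasional transcription or assay outlier that
  heterogeneous literature sources produce, and the aggregation rule is
  otherwise genuinely open.
* **pKa.** Only the strongest macroscopic value is kept: the *minimum* over
  acidic measurements or the *maximum* over basic ones. A molecule carrying
  both acidic and basic annotations is amphoteric and is excluded from the
  pKa dataset entirely. Amphoterics are recognised from the explicit
  qualifiers in the input table; no structure-based protonation inference
  is attempted.
* **Units.** Log-scale properties are stored as base-10 logarithms of the
  native quantity (mol/L, L/kg, mL/min/kg, h). Input columns may arrive
  already transformed (the default assumption, matching the property
  names) or on the native scale via `already_log = FALSE`. Percent
  properties are clamped to [0, 100] when at most 110 — a transcription
  slip such as 104.3% plainly means a high value — and rejected beyond
  that.

## Featurization

Each molecule is represented by a fixed, ordered vector of 207 one- and
two-dimensional descriptors pinned by `descriptor_config()`: OpenBabel
molecular properties (MW, AlogP, TPSA, molar refractivity, hydrogen-bond
counts), elemental and bond composition, ring statistics, simple derived
ratios, and a curated table of SMARTS substructure counts (atom
environments, functional groups, ring systems, short topological paths).
The list is versioned and its hash accompanies every feature matrix, so a
run can assert that training, holdout and prediction calls used the same
representation. The descriptor count is config-overridable; 207 is the
default breadth.

Non-finite descriptor values are imputed with the **training-set medians**,
frozen at training time and reused verbatim at prediction time; a molecule
with more than 20% non-finite descriptors is excluded with a logged reason.
Z-score standardization (again with frozen statistics) is applied where
scale matters: nearest-neighbor distances and the SVR learner. Tree
ensembles consume raw descriptors.

## Splitting

For each property the molecules are partitioned 85 / 7.5 / 7.5:

1. **Least-similar holdout (7.5%).** Each molecule's Euclidean distance to
   its nearest neighbor is computed once on z-scored descriptors over the
   full pool; the molecules with the largest distances are held out, ties
   broken by input order. The distances are a static property of the pool
   — they are not recomputed as molecules are removed, since the quantity
   of interest is each molecule's isolation in the original chemical space.
   Without standardization the distance would be dominated by MW-scale
   descriptors, hence the z-scoring.
2. **Scaffold holdout (7.5%).** Molecules sharing a Murcko framework (ring
   systems plus connecting linkers, side chains removed; computed by
   iterative pruning of terminal heavy atoms, then canonicalized) move as
   whole groups. Groups are accumulated largest-first while they fit under
   the target count; a group that would overshoot is skipped in favour of
   smaller ones, and if the target is still unmet the smallest overshooting
   group closes the holdout provided it overshoots by no more than half its
   own size. Acyclic molecules (empty framework) are never grouped into the
   scaffold holdout. No scaffold in the holdout ever appears in
   train/validation.
3. Everything else is train/validation, split into five equal folds
   (sizes differing by at most one) under an explicit seed — each CV
   iteration trains on 80% of that pool (68% of the total) and validates
   on 20% (17% of the total).

The least-similar stage runs first: its selection is a property of the
full pool, and carving it first keeps the extreme-distance set free of
scaffold-group constraints. Targets are rounded to the nearest integer
with the remainder going to train/validation. A dataset whose largest
scaffold group exceeds the feasible pool errors out rather than producing
a degenerate split.

## Models

Seven regressor families compete under the *same* fold plan (shared folds
make the comparison paired; re-randomizing folds per family would add
between-family noise): support vector regression with an RBF kernel (SVR),
random forest (RFR), extremely randomized trees (ETR), gradient boosting
over depth-limited regression trees (GBR), extreme gradient boosting
(XGBR), oblivious-tree gradient boosting — each boosting step grows a
symmetric decision table, the CatBoost tree shape (CBR) — and AdaBoost.R2
(ABR). SVR, RFR/ETR and XGBR wrap e1071, ranger and xgboost; GBR, CBR and
ABR are implemented in the package over rpart base learners (GBR, ABR) or
a vectorized exhaustive split search over per-feature quantile borders
(CBR). Default hyperparameters are documented package constants, decoupled
from backend-library defaults.

Families are ranked by cross-validated mean MAE (ties: mean RMSE, then
name), the top five enter seeded random-search tuning over per-family
grids, under a wall-clock budget and/or a trial cap. The incumbent
configuration is always retained when no sampled candidate beats it, so
tuning never worsens CV MAE; trial-capped runs are exactly reproducible
under the seed (wall-clock budgets inherently are not, which is why the
trial cap exists). The winner is retrained on the full train/validation
set and evaluated once on each holdout with MAE, RMSE and Spearman rank
correlation. Every fit call records the molecule identifiers it saw; the
test suite asserts that no holdout molecule ever entered any fit.

## ATC profiling

ATC codes are validated against the WHO pattern (level 1 a single
anatomical letter, then two digits, one letter, one letter, two digits).
A drug may carry several codes and then counts in every matching class,
but only once in Global aggregates, which are computed over unique drugs.
The completeness matrix reports, per level-1 class and experimentally
collected property, the percentage of the class's drugs with at least one
curated value; a class's Global entry is the mean of its per-property
percentages (equivalently, the fill fraction of its drug-property cells),
and empty classes are reported as missing rather than zero.

Distribution comparisons use the two-sided Mann-Whitney test: exact (full
enumeration, as implemented in `stats::wilcox.test`) when the combined
sample is at most 12 without ties, otherwise the normal approximation with
tie and continuity corrections. The crossover at 12 keeps the exact branch
cheap while covering the sample sizes where the approximation is weakest.
P values are annotated `ns` (p > 0.05), `*`, `**`, `***`, `****`
(p <= 1e-4) without multiple-testing correction — the annotation mirrors
how such panels are conventionally labelled, and the bins partition (0, 1]
exactly. Boxplot statistics use linear-interpolation quartiles
(`quantile` type 7, the common plotting default), whiskers at the most
extreme points within 1.5 interquartile ranges, outliers beyond. Classes
with fewer than five experimental points (configurable) are reported as
"insufficient data" rather than tested: below that, a rank test is
uninformative. Predicted distributions retain molecules that also have
experimental values — the comparison is sparse-experimental versus
full-coverage-predicted.

## The synthetic-data generator

`synthetic_spec()` defines the study conditions: molecules are enumerated
from a fixed internal library of 24 ring scaffolds decorated with small
substituents, optionally joined pairwise through short linkers (which makes
the Murcko-framework population heavy-tailed — a few large groups plus many
small ones — as in real drug-like collections). Property values follow

y = intercept + sum_d w_d * z(descriptor_d) + class_shift + N(0, sigma)

with z-scores over the generated pool, additive shifts for ATC level-1
class membership, percent-scale clamping to [0, 100], replicate rows with
small jitter at a configurable rate, and for pKa an acidic/basic qualifier
per molecule with a configurable fraction of amphoterics (both rows) that
curation must exclude. The linear form is chosen deliberately: the
irreducible error of the best predictor is then exactly
sigma * sqrt(2/pi) in MAE, so model-recovery checks have an analytic
floor, and injected class shifts have known effect sizes, so profiling
power is predictable. Everything is deterministic under the spec seed.

Default generative models (e.g. logS decreasing in AlogP and MW with noise
sd 0.5 log units; percent properties with sd 10) were set once to
plausible magnitudes for curated literature data of these properties.

What the generator does *not* emulate: real marketed-drug property
distributions, real ATC class populations, activity cliffs,
measurement-protocol heterogeneity, or any nonlinearity beyond what the
descriptor correlations induce. Tests passing on synthetic data therefore
demonstrate that the machinery is correct and well calibrated — not that
the models would reach any particular accuracy on real data.

## Numerical and design choices

* Quartiles: type-7 linear interpolation; Mann-Whitney exact/approximate
  crossover at combined n = 12; annotation bins closed on the right.
* Split rounding: nearest integer per holdout, remainder to
  train/validation; fold sizes differ by at most one.
* Tie-breaks are stable everywhere (input order for equal nearest-neighbor
  distances, size-then-first-occurrence for scaffold groups, RMSE then
  family name for equal MAE).
* Zero-variance descriptors standardize to zero instead of dividing by
  zero; constant targets make Spearman undefined and are reported as
  missing with a warning.
* The problem sizes exercised by the test suite — 1000 molecules for
  split-fraction checks, 2000 for parameter recovery, 200 per class for
  profiling power, trial-capped tuning — are the package's chosen study
  scales for its synthetic validation experiments.
* OpenBabel stops reading a SMILES stream at the first malformed record;
  the canonicalizer therefore retries missing molecules individually so
  one bad row cannot shadow later ones.

## Known limitations

* The descriptor list, while 207 names wide, is OpenBabel-derived and not
  interchangeable with any other toolkit's list; models are only valid
  with the descriptor configuration (and hash) they were trained with.
* The Murcko implementation prunes all terminal atoms, so exocyclic
  double-bonded substituents (e.g. a ring ketone oxygen) are not part of
  the framework; this merges slightly more molecules per scaffold than
  conventions that retain attachment double bonds.
* AlogP here is OpenBabel's atom-contribution logP; other toolkits'
  values differ systematically by a few tenths of a log unit.
* The least-similar holdout is extrapolative by construction; tree
  ensembles saturate outside the training range, so noise-floor recovery
  is expected (and asserted) on the scaffold holdout, not there.
* Tuning grids are small and discrete; with large budgets a continuous
  search would find marginally better configurations.

## A small worked run

```{r example, eval = FALSE}
spec <- synthetic_spec(n_molecules = 300, seed = 42,
                       properties = c("logS", "pKa"))
sim <- simulate_dataset(spec)
cfg <- run_config(properties = "logS", hpo_max_trials = 2)
res <- run_pipeline(cfg, tempdir(), measurements = sim$measurements)
res$results$logS$report
res$profiling$completeness
```
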