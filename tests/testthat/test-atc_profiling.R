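# ATC parsing, significance annotation, Mann-Whitney, boxplot statistics,
# completeness and class profiling.

test_that("ATC codes parse with correct levels and parent chains", {
  expect_equal(parse_atc("N")$level, 1L)
  n05a <- parse_atc("N05A")
  expect_equal(n05a$level, 3L)
  expect_equal(n05a$parents, c("N", "N05"))
  expect_equal(parse_atc("N05AH04")$level, 5L)
  expect_error(parse_atc("5N"), "position 1")
  expect_error(parse_atc("NA"), "position 2")  # digit expected after the letter
  expect_error(parse_atc("N0"), "length")      # length 2 is not a valid level
  expect_error(parse_atc("N0X"), "position 3")
  expect_error(parse_atc("E05"), "position 1") # E is not an anatomical group
  expect_equal(atc_level("N05AH04"), 5L)
})

test_that("annotation bins are exhaustive, exclusive and match the convention", {
  expect_equal(annotate_p(c(0.2, 0.05, 0.03, 0.01, 0.005, 0.001, 5e-4, 1e-4, 1e-5)),
               c("ns", "*", "*", "**", "**", "***", "***", "****", "****"))
  set.seed(5)
  p <- runif(1e4, min = .Machine$double.eps)
  ann <- annotate_p(p)
  expect_true(all(ann %in% c("ns", "*", "**", "***", "****")))
  expect_false(anyNA(ann))
  # bin boundaries re-derived from the annotation are consistent
  expect_true(all(p[ann == "ns"] > 0.05))
  expect_true(all(p[ann == "****"] <= 1e-4))
  expect_error(annotate_p(0), "in \\(0, 1\\]")
})

test_that("Mann-Whitney matches the small-sample enumeration example", {
  cmp <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(unname(cmp$u_statistic), 0)
  expect_equal(cmp$p_value, 1 / 3, tolerance = 1e-12)
  expect_equal(cmp$annotation, "ns")
  expect_true(cmp$exact)
  expect_error(mann_whitney(numeric(0), 1), "non-empty")
})

test_that("exact Mann-Whitney p equals full permutation enumeration", {
  set.seed(19)
  for (na in 2:5) {
    for (nb in 2:(10 - na)) {
      vals <- sample(seq(1, 40, by = 1.5), na + nb)  # tie-free
      a <- vals[seq_len(na)]; b <- vals[-seq_len(na)]
      got <- mann_whitney(a, b)
      expect_true(got$exact)
      expect_equal(got$p_value, oracle_mw_exact_p(a, b), tolerance = 1e-10,
                   label = sprintf("n_a=%d n_b=%d", na, nb))
    }
  }
})

test_that("identical samples are never significant", {
  x <- c(1, 2, 3, 4, 5)
  cmp <- mann_whitney(x, x)
  expect_gt(cmp$p_value, 0.5)
  expect_equal(cmp$annotation, "ns")
})

test_that("boxplot statistics follow the quartile and whisker conventions", {
  bs <- boxplot_stats(1:9)
  expect_equal(bs[c("median", "q1", "q3")], list(median = 5, q1 = 3, q3 = 7))
  expect_length(bs$outliers, 0L)
  expect_equal(bs$whisker_low, 1)
  expect_equal(bs$whisker_high, 9)
  const <- boxplot_stats(rep(4, 6))
  expect_equal(unlist(const[c("median", "q1", "q3", "whisker_low", "whisker_high")]),
               rep(4, 5), ignore_attr = TRUE)
  out <- boxplot_stats(c(1, 2, 3, 4, 100))
  # q3 = 4, IQR = 2, upper fence 7: 100 is an outlier, whisker stops at 4
  expect_equal(out$outliers, 100)
  expect_equal(out$whisker_high, 4)
  # mirror symmetry: negating the data mirrors every statistic
  v <- c(2, 3, 5, 8, 13, 40)
  a <- boxplot_stats(v); b <- boxplot_stats(-v)
  expect_equal(b$median, -a$median)
  expect_equal(b$q1, -a$q3)
  expect_equal(b$whisker_low, -a$whisker_high)
  expect_equal(b$outliers, sort(-a$outliers))
})

test_that("completeness counts multi-class drugs per class but once globally", {
  # six drugs; d1 carries two codes (N02, R05) and the only PPB value
  drugs <- data.frame(
    mol_id = paste0("d", 1:6),
    is_drug = TRUE,
    atc_codes = c("N02;R05", "N02", "N05A", "R03", "R05", "A01"),
    stringsAsFactors = FALSE)
  mk <- function(p, ids, vals) structure(
    list(property = p, unit_spec = "percent",
         values = stats::setNames(vals, ids), n_drugs = length(ids),
         n_non_drugs = 0L), class = "property_dataset")
  datasets <- list(
    PPB = mk("PPB", "d1", 90),
    logS = mk("logS", c("d1", "d2", "d3", "d4"), c(-1, -2, -3, -4)))
  cm <- completeness(drugs, datasets)
  # d1 contributes to both N (3 drugs) and R (3 drugs) PPB cells
  expect_equal(cm["N", "PPB"], round(100 * 1 / 3, 2))
  expect_equal(cm["R", "PPB"], round(100 * 1 / 3, 2))
  # but only once to the global PPB percentage (1 of 6 unique drugs)
  expect_equal(cm["Global", "PPB"], round(100 * 1 / 6, 2))
  expect_equal(cm["N", "logS"], 100)  # d1, d2, d3 all have logS
  expect_equal(cm["A", "logS"], 0)
  # per-class Global column = mean of the class's property percentages
  expect_equal(cm["N", "Global"], round(mean(c(cm["N", "PPB"], cm["N", "logS"])), 2))
  # classes with no drugs are absent rather than zero
  expect_false("B" %in% rownames(cm))
})

test_that("class profiling compares experimental vs predicted and honours drill-down", {
  drugs <- data.frame(
    mol_id = sprintf("d%02d", 1:30), is_drug = TRUE,
    atc_codes = rep(c("N05A", "N05C", "N02"), each = 10),
    stringsAsFactors = FALSE)
  set.seed(31)
  vals <- rnorm(30, 5)
  exper <- structure(list(property = "logBB", unit_spec = "log10_of",
                          values = stats::setNames(vals, drugs$mol_id),
                          n_drugs = 30L, n_non_drugs = 0L),
                     class = "property_dataset")
  # identical experimental and predicted inputs: never significant
  prof <- profile_classes(exper, exper, drugs, level = 1)
  expect_named(prof, "N")
  expect_gt(prof$N$comparison$p_value, 0.9)
  expect_equal(prof$N$comparison$annotation, "ns")
  # drill-down below N05 shows exactly its two children
  prof3 <- profile_classes(exper, exper, drugs, level = 3, parent_class = "N05")
  expect_setequal(names(prof3), c("N05A", "N05C"))
  expect_error(profile_classes(exper, exper, drugs, level = 3,
                               parent_class = "X99"), "")
  # sparse classes are reported as insufficient data, not tested
  sparse <- exper
  sparse$values <- sparse$values[1:3]
  prof_sp <- profile_classes(sparse, exper, drugs, level = 1, min_n = 5)
  expect_identical(prof_sp$N$comparison, "insufficient data")
})

test_that("drug vs non-drug comparison flags an injected shift", {
  set.seed(41)
  mols <- data.frame(mol_id = sprintf("m%03d", 1:200),
                     is_drug = rep(c(TRUE, FALSE), each = 100),
                     stringsAsFactors = FALSE)
  vals <- c(rnorm(100, 1), rnorm(100, 0))
  ds <- structure(list(property = "logCL", unit_spec = "log10_of",
                       values = stats::setNames(vals, mols$mol_id),
                       n_drugs = 100L, n_non_drugs = 100L),
                  class = "property_dataset")
  cmp <- compare_drug_nondrug(ds, mols)
  expect_true(cmp$comparison$annotation != "ns")
  expect_equal(cmp$drug$n, 100)
})
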