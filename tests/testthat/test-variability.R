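# Experimental-variability analyses: replicate SDs, inter-database
# correlation, dataset-composition tests.

test_that("intra-database variability uses the sample SD and an unweighted mean", {
  db <- makeToxDataset(list(CCO = c(1, 2, 3), CCN = 2))
  v <- intraDbVariability(db)
  expect_identical(v$n_multi, 1L)
  # sample SD of {1,2,3} is exactly 1
  expect_identical(v$per_compound$sd, 1)
  expect_identical(v$mean_sd_log, 1)
  # exactly duplicated values collapse at construction (same-study rule),
  # so such a compound is not multi-measured at all
  db0 <- makeToxDataset(list(CCC = c(1, 1), CCO = c(1, 2)))
  expect_identical(intraDbVariability(db0)$n_multi, 1L)
  # SDs {0.2, 0.4} average to 0.3
  db2 <- makeToxDataset(list(
    CCO = c(1 - 0.2 / sqrt(2), 1 + 0.2 / sqrt(2)),
    CCC = c(2 - 0.4 / sqrt(2), 2 + 0.4 / sqrt(2))))
  expect_equal(intraDbVariability(db2)$mean_sd_log, 0.3, tolerance = 1e-4)
})

test_that("a dataset without replicates yields an empty report, not an error", {
  db <- makeToxDataset(list(CCO = 1, CCC = 2))
  v <- intraDbVariability(db)
  expect_identical(v$n_multi, 0L)
  expect_true(is.na(v$mean_sd_log))
  expect_identical(nrow(v$per_compound), 0L)
})

test_that("mean replicate SD is invariant to record order", {
  fx <- .fix()
  db <- fx$gen$dbA
  rec <- records(db)
  set.seed(8)
  shuffled <- toxDataset(rec[sample(nrow(rec)), ], structures(db), db@name)
  expect_equal(intraDbVariability(shuffled)$mean_sd_log,
               intraDbVariability(db)$mean_sd_log, tolerance = 1e-12)
})

test_that("inter-database correlation excludes values identical at 5 significant digits", {
  # CCC's only value is identical in both databases -> excluded entirely;
  # remaining shared structures correlate on medians
  a <- makeToxDataset(list(CCO = c(1.0, 1.2), CCC = 2, CCN = c(0.5, 0.7),
                           CCCC = c(1.5, 1.6)), "a")
  b <- makeToxDataset(list(CCO = c(1.1, 1.3), CCC = 2, CCN = c(0.6, 0.8),
                           CCCC = c(1.4, 1.7)), "b")
  ic <- interDbCorrelation(a, b)
  expect_identical(ic$n_structures, 3L)
  expect_false(canonicalizeSmiles("CCC") %in% ic$medians$canonical_smiles)
  # a constant shift between databases leaves a perfect correlation with
  # an RMSE equal to the shift
  shift <- makeToxDataset(list(CCO = c(1.1, 1.3), CCN = c(0.6, 0.8),
                               CCCC = c(1.55, 1.72)), "shift")
  base <- makeToxDataset(list(CCO = c(1.0, 1.2), CCN = c(0.5, 0.7),
                              CCCC = c(1.45, 1.62)), "base")
  ic2 <- interDbCorrelation(base, shift)
  expect_equal(ic2$r_squared, 1, tolerance = 1e-6)
  expect_equal(ic2$rmse, 0.1, tolerance = 1e-3)
})

test_that("excluding identical pairs never increases the correlated structure count", {
  fx <- .fix()
  ic <- interDbCorrelation(fx$gen$dbA, fx$gen$dbB)
  shared <- intersect(datasetSmiles(fx$gen$dbA), datasetSmiles(fx$gen$dbB))
  expect_lte(ic$n_structures, length(shared))
  expect_gte(ic$r_squared, 0)
})

test_that("SD-distribution comparison behaves like a two-sample t-test", {
  mk_report <- function(sds) {
    structure(list(dataset = "x", n_multi = length(sds),
                   mean_sd_log = mean(sds),
                   per_compound = data.frame(canonical_smiles = paste0("s", seq_along(sds)),
                                             n = 2L, sd = sds, median = 1)),
              class = "VariabilityReport")
  }
  sds <- c(0.1, 0.3, 0.2, 0.4, 0.25)
  expect_equal(compareSdDistributions(mk_report(sds), mk_report(sds))$p_value, 1)
  # clearly shifted distributions
  set.seed(31)
  lo <- rnorm(20, 0.1, 0.01); hi <- rnorm(20, 10, 0.01)
  expect_lt(compareSdDistributions(mk_report(lo), mk_report(hi))$p_value, 1e-3)
  # insufficient data is an explicit outcome, not an error
  res <- compareSdDistributions(mk_report(0.2), mk_report(sds))
  expect_true(is.na(res$p_value))
  expect_match(res$reason, "insufficient")
})

test_that("small-compound comparison counts heavy atoms and runs a chi-square test", {
  small <- makeToxDataset(list(C = 1, CC = 2, CCO = 3), "small")   # all < 11 atoms
  expect_identical(unname(smallCompoundComparison(small, small, 11)$n_small),
                   c(3L, 3L))
  # equal proportions: no effect
  mix <- makeToxDataset(list(C = 1, CC = 2, CCCCCCCCCCCC = 3), "mix")
  expect_gt(smallCompoundComparison(mix, mix)$p_value, 0.99)
  # a database of large compounds only
  big <- makeToxDataset(list("c1ccc2cc(CC(=O)O)ccc2c1" = 1,
                             "CCCCCCCCCCCC" = 2,
                             "c1ccccc1Oc1ccccc1" = 3), "big")
  res <- smallCompoundComparison(small, big)
  expect_identical(unname(res$n_small), c(3L, 0L))
  expect_lt(res$p_value, 0.05)
  expect_true(res$p_value_yates >= res$p_value)
})
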