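# The prediction engine: neighbour search, uninformative-feature
# removal, local weighted random forest, tiered thresholds, fallback.

test_that("neighbour search excludes the query structure and respects the threshold", {
  tr <- makeToxDataset(list(CCO = 1, OCC = 1.5, CCC = 2, CCCC = 2.5))
  q <- structureFromSmiles("CCO")
  # OCC is the same molecule as the query: never a neighbour
  nb <- findNeighbors(q, tr, threshold = 0.01)
  expect_false(q@canonicalSmiles %in% nb$canonical_smiles)
  # thresholds are inclusive and monotone: 0.5-list is a subset of 0.2-list
  nb5 <- findNeighbors(q, tr, 0.5)
  nb2 <- findNeighbors(q, tr, 0.2)
  expect_true(all(nb5$canonical_smiles %in% nb2$canonical_smiles))
  expect_true(all(nb2$similarity >= 0.2))
  # sorted by descending similarity
  expect_false(is.unsorted(rev(nb2$similarity)))
})

test_that("a lone moderately similar compound appears only at the lower threshold", {
  tr <- makeToxDataset(list("CCCCCCCC" = 1))
  q <- structureFromSmiles("CCC")
  sim <- tanimoto(q, structures(tr)[[1]])
  expect_true(sim >= 0.2 && sim < 0.5)
  expect_identical(nrow(findNeighbors(q, tr, 0.5)), 0L)
  expect_identical(nrow(findNeighbors(q, tr, 0.2)), 1L)
})

test_that("uninformative features are those constant across neighbours", {
  # hexanol and heptanol share an identical environment set; butanol differs
  tr <- makeToxDataset(list(CCCCCCO = 1, CCCCCCCO = 1.2, CCCCO = 2))
  q <- structureFromSmiles("CCCCCO")
  nb <- findNeighbors(q, tr, 0.2)
  expect_identical(nrow(nb), 3L)
  feats <- removeUninformativeFeatures(nb, tr)
  fps <- lapply(nb$canonical_smiles, function(s) structures(tr)[[s]]@fingerprint)
  manual <- setdiff(Reduce(union, fps), Reduce(intersect, fps))
  expect_setequal(feats, manual)
  expect_gt(length(feats), 0L)
  # identical fingerprints across all neighbours -> nothing informative
  tr2 <- makeToxDataset(list(CCCCCCO = 1, CCCCCCCO = 1.2))
  nb2 <- findNeighbors(q, tr2, 0.2)
  expect_identical(removeUninformativeFeatures(nb2, tr2), character())
})

test_that("weighted-mean fallback equals the closed form exactly", {
  # identical fingerprints across neighbours force the fallback
  tr2 <- makeToxDataset(list(CCCCCCO = 1, CCCCCCCO = 2))
  q <- structureFromSmiles("CCCCCO")
  p <- predictLoael(q, tr2, seed = 1)
  expect_true(p@success)
  expect_identical(p@methodUsed, "weighted-mean")
  expect_gt(length(p@warnings), 0L)
  y <- unlist(p@neighbors$measurements)
  w <- rep(p@neighbors$similarity, lengths(p@neighbors$measurements))
  expect_identical(p@value, sum(w * y) / sum(w))
  expect_identical(p@rmse, sqrt(sum(w * (y - p@value)^2) / sum(w)))
})

test_that("a single neighbour yields its own value via the fallback", {
  tr <- makeToxDataset(list("CCCCCCCC" = 2))
  p <- predictLoael("CCCCCC", tr, seed = 1)
  expect_true(p@success)
  expect_identical(p@methodUsed, "weighted-mean")
  expect_identical(p@value, 2)
  expect_identical(p@thresholdUsed, 0.2)
  expect_gt(length(p@warnings), 0L)
})

test_that("neighbours with identical responses give that value with zero RMSE", {
  fx <- .fix()
  # pick a cluster with high within-cluster similarity, set all values equal
  tt <- fx$gen$truth
  cl <- tt[tt$cluster == "cluster04", ]
  tr <- makeToxDataset(stats::setNames(as.list(rep(1.7, nrow(cl))), cl$smiles))
  q <- structures(tr)[[1]]
  tr_rest <- dropStructures(tr, q@canonicalSmiles)
  p <- predictLoael(q, tr_rest, seed = 3)
  expect_true(p@success)
  # all neighbours carry the same stored value (1.7 up to the five
  # significant digit dose rounding), so the model returns it with a
  # zero-width interval
  expect_equal(p@value, 1.7, tolerance = 1e-4)
  expect_equal(p@rmse, 0, tolerance = 1e-9)
  expect_equal(p@intervalLow, p@intervalHigh, tolerance = 1e-8)
})

test_that("tiered procedure: close predictions carry no warning, distant ones do", {
  fx <- .fix()
  tr <- fx$training
  preds <- lapply(datasetSmiles(fx$test)[1:8], function(s) {
    predictLoael(structures(fx$test)[[s]], tr, seed = 17)
  })
  for (p in preds) {
    if (!p@success) next
    warned <- length(p@warnings) > 0L
    distant <- identical(p@thresholdUsed, 0.2) || p@methodUsed == "weighted-mean"
    expect_identical(warned, distant)
    expect_lte(p@intervalLow, p@value)
    expect_gte(p@intervalHigh, p@value)
    expect_equal(p@intervalHigh - p@value, 1.96 * p@rmse, tolerance = 1e-12)
  }
})

test_that("a structurally isolated query gets a typed no-prediction outcome", {
  fx <- .fix()
  iso <- fx$gen$truth$canonical_smiles[fx$gen$truth$cluster == "singleton"][1]
  tr <- dropStructures(fx$training, iso)
  p <- predictLoael(structures(fx$training)[[iso]], tr, seed = 1)
  expect_false(p@success)
  expect_identical(p@methodUsed, "none")
  expect_identical(p@reason, "no similar compounds")
  expect_true(is.na(p@value))
})

test_that("predictions are reproducible under a fixed seed", {
  fx <- .fix()
  q <- structures(fx$test)[[datasetSmiles(fx$test)[2]]]
  p1 <- predictLoael(q, fx$training, seed = 99)
  p2 <- predictLoael(q, fx$training, seed = 99)
  expect_identical(p1@value, p2@value)
  expect_identical(p1@rmse, p2@rmse)
  expect_identical(p1@warnings, p2@warnings)
  # the global RNG stream is left untouched
  set.seed(123); before <- runif(1)
  set.seed(123); predictLoael(q, fx$training, seed = 99); after <- runif(1)
  expect_identical(before, after)
})

test_that("local model bootstrap RMSE tracks the noise scale on a synthetic cluster", {
  # linear feature -> response signal with noise SD 0.3; the bootstrap
  # out-of-sample RMSE of the tuned local model should be within a
  # factor of 2 of the noise SD
  fx <- .fix()
  tt <- fx$gen$truth
  cl <- tt[tt$cluster %in% c("cluster04", "cluster05"), ]
  sigma <- 0.3
  set.seed(42)
  vals <- stats::setNames(lapply(seq_len(nrow(cl)), function(i)
    cl$true_neg_log10[i] + stats::rnorm(3, 0, sigma)), cl$smiles)
  tr <- makeToxDataset(vals)
  q <- structures(tr)[[1]]
  rest <- dropStructures(tr, q@canonicalSmiles)
  nb <- findNeighbors(q, rest, 0.2)
  feats <- removeUninformativeFeatures(nb, rest)
  fit <- fitLocalModel(nb, feats, rest, seed = 7)
  expect_gt(fit$rmse, sigma / 2)
  expect_lt(fit$rmse, sigma * 2)
})

test_that("degenerate local-model inputs raise classed fit errors", {
  fx <- .fix()
  tr <- makeToxDataset(list(CCO = 1, OCC = 1.2, CCC = 2))
  q <- structureFromSmiles("CCN")
  nb <- findNeighbors(q, tr, 0.01)
  expect_error(fitLocalModel(nb[0, ], character(), tr), class = "ra_fit_error")
  expect_error(fitLocalModel(nb, character(), tr), class = "ra_fit_error")
})

test_that("back-conversion to mg/kg inverts the -log10 mmol scale", {
  tr <- makeToxDataset(list("CCCCCCCC" = 2))
  p <- predictLoael("CCCCCC", tr, seed = 1)
  mg <- loaelAsMgPerKg(p)
  mw <- p@query@molWeight
  expect_equal(unname(mg["value"]), 10^(-2) * mw, tolerance = 1e-12)
  expect_lte(mg[["low"]], mg[["value"]])
  expect_gte(mg[["high"]], mg[["value"]])
})
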