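# The read-across engine: neighbour search with tiered similarity
# thresholds, similarity-weighted local random-forest regression,
# weighted-mean fallback, 95% prediction intervals and
# applicability-domain warnings.

#' Engine configuration
#'
#' Tunables of the prediction engine.  The similarity thresholds (0.5
#' close to the applicability domain, 0.2 distant) are the established
#' defaults of the tiered procedure and are not meant to be optimized per
#' dataset.
#'
#' @param thresholdHigh similarity threshold of the first tier.
#' @param thresholdLow fallback threshold; predictions made here carry an
#'   applicability-domain warning.
#' @param minNeighbors minimum number of distinct neighbour structures to
#'   attempt a local random forest (below it the weighted-mean fallback
#'   fires).
#' @param nBoot bootstrap resamples used to tune the features-per-split
#'   hyperparameter and to estimate the local-model RMSE.
#' @param numTrees trees per random forest.
#' @param mtryGrid candidate features-per-split values; `NULL` for the
#'   default grid `floor(sqrt(p), p/3, p/2)` clipped to `[1, p]`.
#' @return a list of class `raControl`.
#' @export
raControl <- function(thresholdHigh = 0.5, thresholdLow = 0.2,
                      minNeighbors = 2L, nBoot = 25L, numTrees = 200L,
                      mtryGrid = NULL) {
  stopifnot(thresholdLow > 0, thresholdLow <= thresholdHigh, thresholdHigh <= 1)
  structure(list(thresholdHigh = thresholdHigh, thresholdLow = thresholdLow,
                 minNeighbors = as.integer(minNeighbors),
                 nBoot = as.integer(nBoot), numTrees = as.integer(numTrees),
                 mtryGrid = mtryGrid),
            class = "raControl")
}

#' Find training neighbours of a query structure
#'
#' Returns every training structure with Tanimoto similarity at or above
#' the threshold, excluding structures identical to the query (by
#' canonical SMILES) so that duplicates of the query never inform its own
#' prediction.  Sorted by decreasing similarity, ties broken by canonical
#' SMILES so the ordering is platform-stable.
#'
#' @param query a [Structure-class] or SMILES string.
#' @param training a [ToxDataset-class].
#' @param threshold similarity threshold in `(0, 1]`.
#' @return data.frame with columns `canonical_smiles`, `similarity` and a
#'   list-column `measurements` of -log10(mmol/kg bw/day) values; zero
#'   rows when nothing is similar.
#' @export
findNeighbors <- function(query, training, threshold) {
  stopifnot(threshold > 0, threshold <= 1)
  if (is.character(query)) query <- structureFromSmiles(query)
  structs <- training@structures
  cans <- names(structs)
  sims <- vapply(structs, function(s) tanimoto(query@fingerprint, s@fingerprint),
                 numeric(1))
  keep <- cans != query@canonicalSmiles & sims >= threshold
  cans <- cans[keep]; sims <- unname(sims[keep])
  ord <- order(-sims, cans, method = "radix")
  cans <- cans[ord]; sims <- sims[ord]
  out <- data.frame(canonical_smiles = cans, similarity = sims,
                    stringsAsFactors = FALSE)
  out$measurements <- lapply(cans, function(s) measurementsFor(training, s))
  out
}

#' Features varying across a neighbour set
#'
#' Uninformative fingerprints -- features with identical presence/absence
#' across all neighbours -- carry no signal for the local model and are
#' removed.  The retained features are exactly those present in some but
#' not all neighbours; the query's own fingerprint plays no role.
#'
#' @param neighbors neighbour data.frame from [findNeighbors()].
#' @param training the [ToxDataset-class] the neighbours come from.
#' @return character vector of informative feature strings (possibly
#'   empty, which signals that no random forest can be fit).
#' @export
removeUninformativeFeatures <- function(neighbors, training) {
  if (!nrow(neighbors)) return(character())
  fps <- lapply(neighbors$canonical_smiles,
                function(s) training@structures[[s]]@fingerprint)
  all_feats <- Reduce(union, fps)
  shared <- Reduce(intersect, fps)
  .csort(setdiff(all_feats, shared))
}

# Training rows of a local model: one row per neighbour measurement with
# a binary feature vector, the -log10 response, and the neighbour's
# similarity as observation weight.
.localRows <- function(neighbors, features, training) {
  fps <- lapply(neighbors$canonical_smiles,
                function(s) training@structures[[s]]@fingerprint)
  nmeas <- lengths(neighbors$measurements)
  X <- do.call(rbind, lapply(seq_len(nrow(neighbors)), function(i) {
    row <- as.numeric(features %in% fps[[i]])
    matrix(rep(row, nmeas[i]), nrow = nmeas[i], byrow = TRUE)
  }))
  colnames(X) <- paste0("f", seq_along(features))
  list(X = X,
       y = unlist(neighbors$measurements),
       w = rep(neighbors$similarity, nmeas),
       group = rep(seq_len(nrow(neighbors)), nmeas))
}

#' Fit the local similarity-weighted random forest
#'
#' Builds one training row per neighbour measurement (binary
#' atom-environment descriptors, -log10 LOAEL response, neighbour
#' similarity as observation weight), tunes the features-per-split
#' hyperparameter over a small grid by bootstrap resampling, and
#' estimates the local-model RMSE from the pooled bootstrap out-of-sample
#' residuals.  Resampling is at the neighbour-structure level (all
#' replicate rows of a compound enter or leave a resample together), so
#' the out-of-sample residuals measure compound-level prediction error
#' rather than replicate noise alone.  That RMSE is what the 95%
#' prediction interval (value +/- 1.96 RMSE) is built from.
#'
#' Degenerate inputs (fewer than `minNeighbors` distinct structures, no
#' informative feature, random-forest failure) raise a classed
#' `ra_fit_error`, which the tiered procedure in [predictLoael()] catches
#' to trigger the next tier or the weighted-mean fallback.
#'
#' @param neighbors neighbour data.frame from [findNeighbors()].
#' @param features informative features from
#'   [removeUninformativeFeatures()].
#' @param training the [ToxDataset-class] the neighbours come from.
#' @param seed integer seed controlling bootstrap and forest randomness.
#' @param control an [raControl()] list.
#' @return list with elements `model` (a fitted `ranger`), `rmse`,
#'   `mtry`, `features`.
#' @export
fitLocalModel <- function(neighbors, features, training, seed = 42L,
                          control = raControl()) {
  if (nrow(neighbors) < control$minNeighbors)
    .fitError(sprintf("local model needs >= %d distinct neighbour structures",
                      control$minNeighbors))
  if (!length(features))
    .fitError("no informative features across neighbours")
  rows <- .localRows(neighbors, features, training)
  n <- length(rows$y)
  if (n < 2L) .fitError("too few training rows for a local model")
  p <- length(features)
  grid <- control$mtryGrid
  if (is.null(grid))
    grid <- unique(pmax(1L, pmin(p, floor(c(sqrt(p), p / 3, p / 2)))))
  dat <- data.frame(.y = rows$y, rows$X, check.names = FALSE)

  fit_ranger <- function(d, w, mtry, s) {
    ranger::ranger(
      dependent.variable.name = ".y", data = d, mtry = mtry,
      num.trees = control$numTrees, case.weights = w,
      seed = s, num.threads = 1L)
  }

  # Bootstrap at the neighbour-structure level: all measurement rows of a
  # compound enter or leave a resample together, so out-of-sample residuals
  # reflect compound-level prediction error, not just replicate noise.
  nG <- nrow(neighbors)
  res <- tryCatch(.withSeed(seed, {
    boot_idx <- lapply(seq_len(control$nBoot), function(b) {
      g <- sample.int(nG, nG, replace = TRUE)
      unlist(lapply(g, function(gi) which(rows$group == gi)))
    })
    rmse_grid <- vapply(grid, function(m) {
      sq <- unlist(lapply(seq_along(boot_idx), function(b) {
        idx <- boot_idx[[b]]
        oob <- which(!rows$group %in% rows$group[idx])
        if (!length(oob)) return(numeric())
        fit <- fit_ranger(dat[idx, , drop = FALSE], rows$w[idx], m,
                          s = seed + b)
        pr <- predict(fit, dat[oob, -1, drop = FALSE],
                      num.threads = 1L, seed = seed + b)$predictions
        (pr - rows$y[oob])^2
      }))
      if (!length(sq)) Inf else sqrt(mean(sq))
    }, numeric(1))
    best <- grid[which.min(rmse_grid)]
    final <- fit_ranger(dat, rows$w, best, s = seed)
    list(model = final, rmse = min(rmse_grid), mtry = best,
         features = features)
  }), error = function(e) e)
  if (inherits(res, "error")) {
    if (inherits(res, "ra_fit_error")) stop(res)
    .fitError(paste("random forest failed:", conditionMessage(res)))
  }
  if (!is.finite(res$rmse)) .fitError("bootstrap produced no out-of-sample rows")
  res
}

# Apply a fitted local model to the query fingerprint.  A fixed seed is
# passed so predict.ranger never draws one from (and thereby advances)
# the caller's RNG stream.
.predictLocal <- function(fit, query, seed = 42L) {
  x <- as.data.frame(matrix(as.numeric(fit$features %in% query@fingerprint),
                            nrow = 1L))
  names(x) <- paste0("f", seq_along(fit$features))
  as.numeric(predict(fit$model, x, num.threads = 1L,
                     seed = seed)$predictions)
}

# Similarity-weighted mean of all neighbour measurements, with the
# weighted RMS deviation about that mean as the RMSE estimate.
.weightedMean <- function(neighbors) {
  y <- unlist(neighbors$measurements)
  w <- rep(neighbors$similarity, lengths(neighbors$measurements))
  value <- sum(w * y) / sum(w)
  rmse <- sqrt(sum(w * (y - value)^2) / sum(w))
  list(value = value, rmse = rmse)
}

.newPrediction <- function(query, success, value = NA_real_, rmse = NA_real_,
                           threshold = NA_real_, method = "none",
                           warnings = character(), reason = character(),
                           neighbors = data.frame()) {
  new("LoaelPrediction", query = query, success = success,
      value = value,
      intervalLow = if (is.na(value)) NA_real_ else value - 1.96 * rmse,
      intervalHigh = if (is.na(value)) NA_real_ else value + 1.96 * rmse,
      rmse = rmse, thresholdUsed = threshold, methodUsed = method,
      warnings = warnings, reason = reason, neighbors = neighbors)
}

#' Predict the LOAEL of a query structure by read-across
#'
#' The tiered procedure: (1) collect neighbours at similarity >= 0.5 and
#' fit a local weighted random forest -- a success here is a prediction
#' close to the applicability domain, without warnings; (2) if any step
#' fails, repeat at threshold 0.2 and flag the prediction with an
#' applicability-domain warning; (3) if random-forest modelling fails at
#' the lower tier too, fall back to the similarity-weighted mean of all
#' neighbour measurements, with an additional warning; (4) if no
#' neighbour exists even at 0.2, return an unsuccessful prediction with
#' reason `"no similar compounds"` rather than an error.  Every
#' successful prediction carries the 95% prediction interval value +/-
#' 1.96 x RMSE of its local model.
#'
#' Training records whose canonical SMILES equals the query's are always
#' excluded from the neighbour search; this leakage guard is hardwired
#' into the engine and cannot be disabled.
#'
#' @param query SMILES string or [Structure-class].
#' @param training a preprocessed [ToxDataset-class].
#' @param seed integer seed; identical (query, training, seed) yield an
#'   identical prediction.
#' @param control an [raControl()] list.
#' @return a [LoaelPrediction-class].
#' @examples
#' \dontrun{
#' p <- predictLoael("CCOc1ccccc1", training, seed = 1)
#' p
#' }
#' @export
predictLoael <- function(query, training, seed = 42L, control = raControl()) {
  if (is.character(query)) query <- structureFromSmiles(query)
  stopifnot(is(query, "Structure"), is(training, "ToxDataset"))

  try_rf <- function(nb) {
    feats <- removeUninformativeFeatures(nb, training)
    fit <- fitLocalModel(nb, feats, training, seed = seed, control = control)
    list(value = .predictLocal(fit, query, seed = seed), rmse = fit$rmse)
  }

  nb1 <- findNeighbors(query, training, control$thresholdHigh)
  if (nrow(nb1)) {
    rf <- tryCatch(try_rf(nb1), ra_fit_error = function(e) NULL)
    if (!is.null(rf))
      return(.newPrediction(query, TRUE, rf$value, rf$rmse,
                            threshold = control$thresholdHigh,
                            method = "local-rf", neighbors = nb1))
  }

  nb2 <- findNeighbors(query, training, control$thresholdLow)
  if (!nrow(nb2))
    return(.newPrediction(query, FALSE, reason = "no similar compounds"))

  ad_warning <- sprintf(
    "similarity threshold lowered to %s: prediction may be out of the applicability domain",
    format(control$thresholdLow))
  rf <- tryCatch(try_rf(nb2), ra_fit_error = function(e) NULL)
  if (!is.null(rf))
    return(.newPrediction(query, TRUE, rf$value, rf$rmse,
                          threshold = control$thresholdLow,
                          method = "local-rf", warnings = ad_warning,
                          neighbors = nb2))

  wm <- .weightedMean(nb2)
  .newPrediction(query, TRUE, wm$value, wm$rmse,
                 threshold = control$thresholdLow, method = "weighted-mean",
                 warnings = c(ad_warning,
                              "local random forest failed: similarity-weighted mean used"),
                 neighbors = nb2)
}

#' Back-convert a prediction to mg/kg bw/day
#'
#' @param prediction a successful [LoaelPrediction-class].
#' @return named vector `value`, `low`, `high` in mg/kg bw/day (note the
#'   interval flips: a higher -log10 potency is a lower dose).
#' @export
loaelAsMgPerKg <- function(prediction) {
  stopifnot(is(prediction, "LoaelPrediction"), prediction@success)
  mw <- prediction@query@molWeight
  c(value = 10^(-prediction@value) * mw,
    low   = 10^(-prediction@intervalHigh) * mw,
    high  = 10^(-prediction@intervalLow) * mw)
}
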