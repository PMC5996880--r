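# Leakage-proof validation: test-set evaluation against per-compound
# experimental medians, repeated structure-level k-fold cross-validation,
# and correlation statistics, all stratified by applicability-domain tier
# (ad-close = no warnings, ad-distant = warned predictions).

#' Correlation statistics between predicted and observed values
#'
#' @param predicted,observed equal-length numeric vectors, `n >= 3`.
#' @return list with `r_squared` (squared Pearson correlation), `rmse`
#'   (root mean squared difference), `p_value` (correlation test), `n`.
#' @export
correlationStats <- function(predicted, observed) {
  if (length(predicted) != length(observed))
    .configError("predicted and observed must have equal length")
  if (length(predicted) < 3L)
    .configError("correlation needs at least 3 pairs")
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0)
    .raError("correlation undefined for a constant vector",
             class = "ra_constant_error")
  ct <- stats::cor.test(predicted, observed)
  list(r_squared = unname(ct$estimate)^2,
       rmse = sqrt(mean((predicted - observed)^2)),
       p_value = ct$p.value,
       n = length(predicted))
}

# Tier label of a prediction: ad-close (no warnings), ad-distant
# (warnings), failed.
.tierOf <- function(p) {
  if (!p@success) "failed"
  else if (length(p@warnings)) "ad-distant"
  else "ad-close"
}

# Summarize a per-compound prediction table into tier-stratified
# validation rows.  pi_coverage pools individual experimental
# measurements (a compound with 3 studies contributes 3 coverage
# checks).
.summarizeTiers <- function(preds) {
  ok <- preds[preds$tier != "failed", , drop = FALSE]
  one <- function(tier, d) {
    cs <- if (nrow(d) >= 3L && stats::sd(d$predicted) > 0 &&
              stats::sd(d$observed_median) > 0)
      correlationStats(d$predicted, d$observed_median)
    else list(r_squared = NA_real_,
              rmse = if (nrow(d)) sqrt(mean((d$predicted - d$observed_median)^2))
                     else NA_real_,
              p_value = NA_real_, n = nrow(d))
    data.frame(tier = tier, r_squared = cs$r_squared, rmse = cs$rmse,
               p_value = cs$p_value, n_predicted = nrow(d),
               n_attempted = nrow(preds),
               pi_coverage = if (sum(d$n_measurements))
                 sum(d$n_inside) / sum(d$n_measurements) else NA_real_,
               stringsAsFactors = FALSE)
  }
  rbind(one("ad-close", ok[ok$tier == "ad-close", , drop = FALSE]),
        one("ad-distant", ok[ok$tier == "ad-distant", , drop = FALSE]),
        one("all", ok))
}

# Predict each structure in `targets` (named list of Structure) from
# `training`, scoring against the experimental values in `reference`.
.evaluateStructures <- function(targets, training, reference, seed, control) {
  rows <- lapply(seq_along(targets), function(i) {
    st <- targets[[i]]
    p <- predictLoael(st, training, seed = seed + i, control = control)
    if (st@canonicalSmiles %in% p@neighbors$canonical_smiles)
      stop("leakage: query structure found among its own neighbours")
    meas <- measurementsFor(reference, st@canonicalSmiles)
    inside <- if (p@success)
      sum(meas >= p@intervalLow & meas <= p@intervalHigh) else 0L
    data.frame(canonical_smiles = st@canonicalSmiles,
               predicted = if (p@success) p@value else NA_real_,
               observed_median = stats::median(meas),
               interval_low = p@intervalLow, interval_high = p@intervalHigh,
               tier = .tierOf(p), method = p@methodUsed,
               threshold = p@thresholdUsed,
               n_neighbors = nrow(p@neighbors),
               n_measurements = length(meas), n_inside = inside,
               stringsAsFactors = FALSE)
  })
  preds <- do.call(rbind, rows)
  rownames(preds) <- NULL
  preds
}

#' Evaluate the engine on the test set, leakage-free
#'
#' For every unique test structure, predicts its LOAEL from the training
#' dataset and scores the prediction against the median of the
#' structure's experimental -log10 values.  The engine's hardwired
#' canonical-SMILES exclusion guarantees that none of the query's own
#' training records is used; this is re-asserted here on every neighbour
#' list.  Results are stratified into predictions close to the
#' applicability domain (no warnings), distant (warned), and pooled;
#' failed predictions (no similar compounds) are counted separately.
#'
#' @param test,training [ToxDataset-class] objects; test structures are
#'   expected to occur in training (they are excluded per query).
#' @param seed integer seed.
#' @param control an [raControl()] list.
#' @return list with `predictions` (one row per test structure) and
#'   `summary` (one row per tier, with r-squared, RMSE, counts and
#'   prediction-interval coverage).
#' @export
evaluateTestSet <- function(test, training, seed = 42L, control = raControl()) {
  targets <- structures(test)[datasetSmiles(test)]
  preds <- .evaluateStructures(targets, training, test, seed, control)
  list(predictions = preds, summary = .summarizeTiers(preds))
}

#' Repeated k-fold cross-validation at the structure level
#'
#' Splits the unique structures (never individual measurements: all
#' records of a compound stay in the same fold) into k folds, predicts
#' each held-out structure from the remaining folds, and repeats with
#' independent shuffles.  Scoring is against the median of the
#' structure's experimental values in the full dataset.
#'
#' @param training a [ToxDataset-class].
#' @param k folds, `>= 2`.
#' @param repeats independent repetitions.
#' @param seed integer seed.
#' @param control an [raControl()] list.
#' @return list with `perRepeat` (tier summaries of every repeat) and
#'   `aggregate` (mean and SD of r-squared, RMSE and predicted counts per
#'   tier across repeats).
#' @export
repeatedKfold <- function(training, k = 10L, repeats = 50L, seed = 42L,
                          control = raControl()) {
  smls <- datasetSmiles(training)
  n <- length(smls)
  if (k < 2L) .configError("k must be >= 2")
  if (n < k) .configError("fewer unique structures than folds")
  per <- lapply(seq_len(repeats), function(r) {
    fold <- .withSeed(seed + 1000L * r, sample(rep_len(seq_len(k), n)))
    rows <- lapply(seq_len(k), function(j) {
      held <- smls[fold == j]
      sub <- dropStructures(training, held)
      .evaluateStructures(structures(training)[held], sub, training,
                          seed = seed + 1000L * r + j, control = control)
    })
    s <- .summarizeTiers(do.call(rbind, rows))
    s$repeat_id <- r
    s
  })
  perRepeat <- do.call(rbind, per)
  agg <- do.call(rbind, lapply(split(perRepeat, perRepeat$tier), function(d) {
    data.frame(tier = d$tier[1],
               r_squared_mean = mean(d$r_squared), r_squared_sd = stats::sd(d$r_squared),
               rmse_mean = mean(d$rmse), rmse_sd = stats::sd(d$rmse),
               n_predicted_mean = mean(d$n_predicted),
               n_predicted_sd = stats::sd(d$n_predicted),
               pi_coverage_mean = mean(d$pi_coverage),
               stringsAsFactors = FALSE)
  }))
  rownames(agg) <- NULL
  list(perRepeat = perRepeat, aggregate = agg)
}
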