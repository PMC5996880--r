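# Experimental-variability analyses: replicate standard deviations
# within a database, median correlation between databases, and the two
# dataset-composition tests.  These quantify how reproducible the animal
# studies themselves are, which is the benchmark prediction errors are
# judged against.

#' Intra-database replicate variability
#'
#' For every structure with at least two measurements, the sample
#' standard deviation of its -log10(mmol/kg bw/day) values; the report
#' carries their unweighted mean (each compound counts once, regardless
#' of how many replicates it has).
#'
#' @param db a preprocessed [ToxDataset-class].
#' @return list of class `VariabilityReport`: `dataset`, `n_multi`
#'   (structures with >= 2 measurements), `mean_sd_log`, and
#'   `per_compound` (structure, replicate count, SD, median).  Empty
#'   (with `n_multi = 0`, `mean_sd_log = NA`) when no structure has
#'   replicates.
#' @export
intraDbVariability <- function(db) {
  multi <- .multiMeasured(db)
  per <- do.call(rbind, lapply(multi, function(s) {
    v <- measurementsFor(db, s)
    data.frame(canonical_smiles = s, n = length(v), sd = stats::sd(v),
               median = stats::median(v), stringsAsFactors = FALSE)
  }))
  structure(list(dataset = db@name,
                 n_multi = length(multi),
                 mean_sd_log = if (length(multi)) mean(per$sd) else NA_real_,
                 per_compound = if (length(multi)) per else
                   data.frame(canonical_smiles = character(), n = integer(),
                              sd = numeric(), median = numeric())),
            class = "VariabilityReport")
}

#' @export
print.VariabilityReport <- function(x, ...) {
  cat("Experimental variability of", x$dataset, "\n")
  cat("  structures with multiple measurements:", x$n_multi, "\n")
  cat("  mean replicate SD (-log10 scale):",
      format(x$mean_sd_log, digits = 3), "\n")
  invisible(x)
}

#' Inter-database correlation of median LOAELs
#'
#' For structures occurring in both databases, values identical at five
#' significant digits on the mmol scale in both databases are excluded
#' (they likely originate from the same study and would inflate the
#' apparent agreement).  Per-database medians of the remaining -log10
#' values are then correlated.
#'
#' @param a,b preprocessed [ToxDataset-class] objects.
#' @return list with `r_squared`, `rmse`, `p_value`, `n_structures`, and
#'   `medians` (per-structure median pairs).  If no structure survives
#'   the exclusions, `n_structures` is 0 and the statistics are `NA`.
#' @export
interDbCorrelation <- function(a, b) {
  shared <- intersect(datasetSmiles(a), datasetSmiles(b))
  rows <- lapply(shared, function(s) {
    ra <- a@records[a@records$canonical_smiles == s, , drop = FALSE]
    rb <- b@records[b@records$canonical_smiles == s, , drop = FALSE]
    ka <- .sig5Key(ra$loael_mmol); kb <- .sig5Key(rb$loael_mmol)
    common <- intersect(ka, kb)
    va <- ra$loael_neg_log10[!ka %in% common]
    vb <- rb$loael_neg_log10[!kb %in% common]
    if (!length(va) || !length(vb)) return(NULL)
    data.frame(canonical_smiles = s, median_a = stats::median(va),
               median_b = stats::median(vb), stringsAsFactors = FALSE)
  })
  med <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  if (is.null(med) || nrow(med) < 3L) {
    warning("fewer than 3 shared structures remain after excluding identical values")
    return(list(r_squared = NA_real_, rmse = NA_real_, p_value = NA_real_,
                n_structures = if (is.null(med)) 0L else nrow(med),
                medians = med))
  }
  cs <- correlationStats(med$median_a, med$median_b)
  list(r_squared = cs$r_squared, rmse = cs$rmse, p_value = cs$p_value,
       n_structures = nrow(med), medians = med)
}

#' Compare replicate-SD distributions of two databases
#'
#' Two-sample t-test on the per-compound replicate standard deviations;
#' a non-significant result says the two databases are about equally
#' reproducible.
#'
#' @param a,b `VariabilityReport` objects from [intraDbVariability()].
#' @return list with `p_value`, `statistic`, `n_a`, `n_b`; when either
#'   report has fewer than two multi-measured compounds (or the test is
#'   degenerate) `p_value` is `NA` and `reason` explains why.
#' @export
compareSdDistributions <- function(a, b) {
  if (a$n_multi < 2L || b$n_multi < 2L)
    return(list(p_value = NA_real_, statistic = NA_real_,
                n_a = a$n_multi, n_b = b$n_multi,
                reason = "insufficient data: need >= 2 multi-measured compounds per database"))
  tt <- tryCatch(stats::t.test(a$per_compound$sd, b$per_compound$sd),
                 error = function(e) NULL)
  if (is.null(tt))
    return(list(p_value = NA_real_, statistic = NA_real_,
                n_a = a$n_multi, n_b = b$n_multi,
                reason = "t-test degenerate (essentially constant data)"))
  list(p_value = tt$p.value, statistic = unname(tt$statistic),
       n_a = a$n_multi, n_b = b$n_multi)
}

#' Compare the proportions of small compounds in two databases
#'
#' Counts unique structures with fewer than `cutoff` heavy atoms in each
#' dataset and tests the 2x2 contingency table (small vs not small by
#' dataset) with a chi-square test.  P-values with and without Yates
#' continuity correction are both reported; the uncorrected one is the
#' headline value.
#'
#' @param a,b preprocessed [ToxDataset-class] objects.
#' @param cutoff heavy-atom threshold; compounds with fewer than `cutoff`
#'   non-hydrogen atoms count as small.
#' @return list with `n_small`, `n_structures`, `p_value` (uncorrected),
#'   `p_value_yates`.
#' @export
smallCompoundComparison <- function(a, b, cutoff = 11L) {
  count <- function(db) {
    ha <- vapply(structures(db)[datasetSmiles(db)], slot, 0L, "heavyAtoms")
    c(small = sum(ha < cutoff), total = length(ha))
  }
  ca <- count(a); cb <- count(b)
  tab <- rbind(c(ca["small"], ca["total"] - ca["small"]),
               c(cb["small"], cb["total"] - cb["small"]))
  p_plain <- suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  p_yates <- suppressWarnings(stats::chisq.test(tab, correct = TRUE)$p.value)
  list(n_small = c(ca["small"], cb["small"]),
       n_structures = c(ca["total"], cb["total"]),
       p_value = p_plain, p_value_yates = p_yates)
}
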