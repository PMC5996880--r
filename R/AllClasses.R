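#' @import methods
NULL

#' Chemical structure with MolPrint2D fingerprint
#'
#' Container for a single parsed structure: the SMILES as given, its
#' OpenBabel canonical SMILES (used throughout for duplicate detection),
#' the set of MolPrint2D atom-environment feature strings, the average
#' molecular weight (g/mol, implicit hydrogens included) and the number
#' of heavy (non-hydrogen) atoms.
#'
#' @slot inputSmiles SMILES string as supplied by the user or data file.
#' @slot canonicalSmiles OpenBabel canonical SMILES.
#' @slot fingerprint character vector, the set of distinct atom-environment
#'   feature strings (one environment per heavy atom, duplicates collapsed).
#' @slot molWeight average molecular weight in g/mol.
#' @slot heavyAtoms number of non-hydrogen atoms.
#'
#' @seealso [structureFromSmiles()], [molprint2d()], [tanimoto()]
#' @export
setClass("Structure",
  representation(
    inputSmiles     = "character",
    canonicalSmiles = "character",
    fingerprint     = "character",
    molWeight       = "numeric",
    heavyAtoms      = "integer"
  )
)

setValidity("Structure", function(object) {
  msg <- character()
  if (length(object@canonicalSmiles) != 1L || !nzchar(object@canonicalSmiles))
    msg <- c(msg, "canonicalSmiles must be a single non-empty string")
  if (object@heavyAtoms < 1L)
    msg <- c(msg, "a valid structure has at least one heavy atom")
  if (!length(object@fingerprint))
    msg <- c(msg, "fingerprint must be non-empty for a molecule with >= 1 heavy atom")
  if (length(object@fingerprint) > object@heavyAtoms)
    msg <- c(msg, "fingerprint cannot contain more environments than heavy atoms")
  if (!isTRUE(object@molWeight > 0))
    msg <- c(msg, "molWeight must be positive")
  if (anyDuplicated(object@fingerprint))
    msg <- c(msg, "fingerprint must be a set (no duplicate features)")
  if (length(msg)) msg else TRUE
})

#' @describeIn Structure-class compact display
#' @param object a `Structure`
#' @export
setMethod("show", "Structure", function(object) {
  cat("Structure:", object@canonicalSmiles, "\n")
  cat("  heavy atoms:", object@heavyAtoms,
      " MW:", format(object@molWeight, digits = 6), "g/mol\n")
  cat("  MolPrint2D environments:", length(object@fingerprint), "\n")
})

#' Named collection of LOAEL measurements
#'
#' A `ToxDataset` holds one toxicity database: one row per study-level
#' LOAEL measurement (a compound can occur many times), plus the parsed
#' [Structure-class] object for every distinct canonical SMILES.  All
#' doses are stored in mmol/kg body weight/day rounded to five
#' significant digits, together with their -log10 transform, which is the
#' working scale for modelling and validation.
#'
#' Records that share both the canonical structure and the dose value at
#' five significant digits are treated as duplicates originating from the
#' same study and collapsed to a single record at construction time.
#'
#' @slot name dataset label, e.g. `"nestle"`.
#' @slot records data.frame with columns `input_smiles`, `canonical_smiles`,
#'   `loael_mmol`, `loael_neg_log10`, `source`, `original_value`,
#'   `original_unit`.
#' @slot structures named list of [Structure-class] objects keyed by
#'   canonical SMILES; covers every structure appearing in `records`.
#' @slot meta list of provenance information: canonicalisation dialect,
#'   rejected rows, counts of dropped empty entries.
#'
#' @seealso [readLoaelTable()], [buildTrainingSet()], [buildTestSet()]
#' @export
setClass("ToxDataset",
  representation(
    name       = "character",
    records    = "data.frame",
    structures = "list",
    meta       = "list"
  )
)

.REQUIRED_RECORD_COLS <- c("input_smiles", "canonical_smiles", "loael_mmol",
                           "loael_neg_log10", "source", "original_value",
                           "original_unit")

setValidity("ToxDataset", function(object) {
  msg <- character()
  rec <- object@records
  missing <- setdiff(.REQUIRED_RECORD_COLS, names(rec))
  if (length(missing))
    msg <- c(msg, paste("records is missing columns:", paste(missing, collapse = ", ")))
  if (!length(msg) && nrow(rec)) {
    if (any(!is.finite(rec$loael_mmol)) || any(rec$loael_mmol <= 0))
      msg <- c(msg, "all loael_mmol values must be positive and finite")
    else if (max(abs(rec$loael_neg_log10 + log10(rec$loael_mmol))) > 1e-9)
      msg <- c(msg, "loael_neg_log10 must equal -log10(loael_mmol)")
    uncovered <- setdiff(unique(rec$canonical_smiles), names(object@structures))
    if (length(uncovered))
      msg <- c(msg, paste("structures missing for:", paste(utils::head(uncovered, 3), collapse = ", ")))
    if (!all(vapply(object@structures, is, TRUE, "Structure")))
      msg <- c(msg, "structures must all be Structure objects")
    key <- paste(rec$canonical_smiles, .sig5Key(rec$loael_mmol))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (structure, value at 5 significant digits) records present")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn ToxDataset-class compact display
#' @param object a `ToxDataset`
#' @export
setMethod("show", "ToxDataset", function(object) {
  cat("ToxDataset:", object@name, "\n")
  cat("  ", nrow(object@records), "LOAEL records /",
      length(unique(object@records$canonical_smiles)), "unique structures\n")
  nm <- length(.multiMeasured(object))
  cat("  ", nm, "structures with multiple measurements\n")
  if (!is.null(object@meta$rejects) && nrow(object@meta$rejects))
    cat("  ", nrow(object@meta$rejects), "rejected input rows (unparsable SMILES)\n")
})

#' Read-across prediction for one query structure
#'
#' Result of the tiered prediction procedure: a point estimate on the
#' -log10(mmol/kg bw/day) scale, a 95% prediction interval (value +/-
#' 1.96 x RMSE of the local model), the similarity threshold that finally
#' produced the prediction, the modelling method used, applicability-domain
#' warnings, and the neighbour table used for the local model.  A query
#' without any neighbour at the lowest threshold yields an unsuccessful
#' prediction (`success = FALSE`) with the reason recorded rather than an
#' error.
#'
#' @slot query the query [Structure-class].
#' @slot success logical, `FALSE` when no prediction could be made.
#' @slot value predicted -log10(mmol/kg bw/day); `NA` on failure.
#' @slot intervalLow,intervalHigh bounds of the 95% prediction interval.
#' @slot rmse local-model RMSE estimate underlying the interval.
#' @slot thresholdUsed similarity threshold of the successful tier (0.5 or
#'   0.2); `NA` on failure.
#' @slot methodUsed `"local-rf"`, `"weighted-mean"` or `"none"`.
#' @slot warnings character vector of applicability-domain warnings; empty
#'   for predictions close to the applicability domain.
#' @slot reason explanation when `success` is `FALSE`.
#' @slot neighbors data.frame of neighbours (canonical SMILES, similarity,
#'   list-column of -log10 measurements) used for the prediction.
#'
#' @seealso [predictLoael()]
#' @export
setClass("LoaelPrediction",
  representation(
    query         = "Structure",
    success       = "logical",
    value         = "numeric",
    intervalLow   = "numeric",
    intervalHigh  = "numeric",
    rmse          = "numeric",
    thresholdUsed = "numeric",
    methodUsed    = "character",
    warnings      = "character",
    reason        = "character",
    neighbors     = "data.frame"
  )
)

setValidity("LoaelPrediction", function(object) {
  msg <- character()
  if (isTRUE(object@success)) {
    if (!is.finite(object@value))
      msg <- c(msg, "successful prediction must carry a finite value")
    else if (object@intervalLow > object@value || object@value > object@intervalHigh)
      msg <- c(msg, "interval must contain the point prediction")
    warned <- length(object@warnings) > 0L
    distant <- identical(object@thresholdUsed, 0.2) ||
      identical(object@methodUsed, "weighted-mean")
    if (warned != distant)
      msg <- c(msg, "warnings must be present exactly for threshold 0.2 or weighted-mean predictions")
  }
  if (length(msg)) msg else TRUE
})

#' @describeIn LoaelPrediction-class compact display
#' @param object a `LoaelPrediction`
#' @export
setMethod("show", "LoaelPrediction", function(object) {
  cat("LoaelPrediction for", object@query@canonicalSmiles, "\n")
  if (!object@success) {
    cat("  no prediction:", object@reason, "\n")
    return(invisible(NULL))
  }
  mg <- loaelAsMgPerKg(object)
  cat(sprintf("  -log10(mmol/kg bw/day): %.3f  [%.3f, %.3f]\n",
              object@value, object@intervalLow, object@intervalHigh))
  cat(sprintf("  mg/kg bw/day:           %.4g  [%.4g, %.4g]\n",
              mg["value"], mg["low"], mg["high"]))
  cat("  method:", object@methodUsed,
      " similarity threshold:", object@thresholdUsed,
      " neighbours:", nrow(object@neighbors), "\n")
  if (length(object@warnings))
    cat("  warnings:", paste(object@warnings, collapse = "; "), "\n")
  else cat("  within applicability domain (no warnings)\n")
})
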