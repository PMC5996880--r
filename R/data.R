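# Dataset construction: reading LOAEL tables, unit conversion, -log10
# transform, five-significant-digit duplicate removal, and the derived
# training (union) and test (intersection) datasets.

#' Convert a dose from mg/kg bw/day to mmol/kg bw/day
#'
#' Divides by the molecular weight and rounds to five significant digits.
#' Rounding happens here, once, before any duplicate comparison.
#'
#' @param value dose in mg/kg bw/day, positive.
#' @param mw molecular weight in g/mol, positive.
#' @return dose in mmol/kg bw/day, five significant digits.
#' @examples
#' convertUnits(50, 100)  # 0.5
#' @export
convertUnits <- function(value, mw) {
  if (any(!is.finite(value)) || any(value <= 0))
    .configError("dose values must be positive and finite")
  if (any(!is.finite(mw)) || any(mw <= 0))
    .configError("molecular weights must be positive and finite")
  signif(value / mw, 5L)
}

#' Negative decadic logarithm of a molar dose
#'
#' @param value dose in mmol/kg bw/day, positive.
#' @return `-log10(value)`; higher means more potent.
#' @export
negLog10 <- function(value) {
  if (any(!is.finite(value)) || any(value <= 0))
    .configError("doses must be positive to be -log10 transformed")
  -log10(value)
}

# Collapse records equal in (canonical structure, dose at 5 significant
# digits); such pairs are taken to originate from the same study.
.dedupRecords <- function(records) {
  key <- paste(records$canonical_smiles, .sig5Key(records$loael_mmol))
  records[!duplicated(key), , drop = FALSE]
}

#' Construct a ToxDataset from records and parsed structures
#'
#' Low-level constructor: applies duplicate removal and validates.  Most
#' users will call [readLoaelTable()] instead.
#'
#' @param records data.frame with the record columns documented in
#'   [ToxDataset-class].
#' @param structures named list of [Structure-class] objects keyed by
#'   canonical SMILES.
#' @param name dataset label.
#' @param meta optional provenance list.
#' @return a [ToxDataset-class].
#' @export
toxDataset <- function(records, structures, name, meta = list()) {
  records <- .dedupRecords(records)
  rownames(records) <- NULL
  structures <- structures[unique(records$canonical_smiles)]
  if (is.null(meta$canonicalization))
    meta$canonicalization <- "OpenBabel canonical SMILES (ChemmineOB)"
  new("ToxDataset", name = name, records = records,
      structures = structures, meta = meta)
}

#' Read a delimited LOAEL table into a ToxDataset
#'
#' Reads a delimited text file with a header, drops rows with empty or
#' undefined LOAEL entries (count recorded in `meta`), canonicalizes the
#' SMILES, converts doses to mmol/kg bw/day (rounded to five significant
#' digits), adds the -log10 transform, and removes duplicate records.
#' Rows whose SMILES fail to parse are excluded and collected into a
#' rejects report in `meta$rejects` rather than silently dropped.
#'
#' @param path file path.
#' @param smilesColumn,valueColumn column names in the header.
#' @param unit unit of the value column: `"mg/kg"` (converted via the
#'   computed molecular weight) or `"mmol/kg"` (rounded only).
#' @param name dataset label; defaults to the file name.
#' @param sep field separator.
#' @param scheme fingerprint atom typing scheme, see [structureFromSmiles()].
#' @return a [ToxDataset-class].
#' @export
readLoaelTable <- function(path, smilesColumn = "SMILES",
                           valueColumn = "LOAEL",
                           unit = c("mg/kg", "mmol/kg"),
                           name = NULL, sep = ",",
                           scheme = "element-aromatic") {
  unit <- match.arg(unit)
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        stringsAsFactors = FALSE)
  missing <- setdiff(c(smilesColumn, valueColumn), names(df))
  if (length(missing))
    .configError(sprintf("columns not found in '%s': %s", path,
                         paste(missing, collapse = ", ")))
  smiles <- as.character(df[[smilesColumn]])
  value <- suppressWarnings(as.numeric(df[[valueColumn]]))
  keep <- !is.na(value) & value > 0 & !is.na(smiles) & nzchar(smiles)
  n_dropped <- sum(!keep)
  smiles <- smiles[keep]; value <- value[keep]

  parsed <- parseStructures(unique(smiles), scheme = scheme, onError = "collect")
  rejects <- attr(parsed, "rejects")
  ok <- smiles %in% names(parsed)
  reject_rows <- data.frame(input_smiles = smiles[!ok],
                            value = value[!ok], stringsAsFactors = FALSE)
  smiles <- smiles[ok]; value <- value[ok]

  structs <- parsed[smiles]
  can <- vapply(structs, slot, "", "canonicalSmiles")
  mw <- vapply(structs, slot, 0, "molWeight")
  mmol <- if (unit == "mg/kg") convertUnits(value, mw) else signif(value, 5L)

  records <- data.frame(
    input_smiles = smiles,
    canonical_smiles = unname(can),
    loael_mmol = mmol,
    loael_neg_log10 = negLog10(mmol),
    source = name,
    original_value = value,
    original_unit = unit,
    stringsAsFactors = FALSE
  )
  structures <- structs[!duplicated(can)]
  names(structures) <- can[!duplicated(can)]
  toxDataset(records, structures, name,
             meta = list(rejects = reject_rows, n_dropped_empty = n_dropped,
                         path = path))
}

#' @rdname accessors
#' @export
recordCount <- function(x) nrow(x@records)

#' Dataset accessors
#'
#' `recordCount` and `structureCount` return the number of LOAEL records
#' and distinct canonical structures; `datasetSmiles` the canonical
#' SMILES; `measurementsFor` the -log10 measurement vector of one
#' structure; `records` and `structures` the underlying containers.
#'
#' @param x a [ToxDataset-class].
#' @param smiles a canonical SMILES present in the dataset.
#' @name accessors
#' @export
structureCount <- function(x) length(unique(x@records$canonical_smiles))

#' @rdname accessors
#' @export
datasetSmiles <- function(x) unique(x@records$canonical_smiles)

#' @rdname accessors
#' @export
measurementsFor <- function(x, smiles) {
  x@records$loael_neg_log10[x@records$canonical_smiles == smiles]
}

#' @rdname accessors
#' @export
records <- function(x) x@records

#' @rdname accessors
#' @export
structures <- function(x) x@structures

# canonical smiles of structures with >= 2 measurements
.multiMeasured <- function(x) {
  tab <- table(x@records$canonical_smiles)
  names(tab)[tab >= 2L]
}

#' Restrict a dataset to (or purge it of) a set of structures
#'
#' `keepStructures` retains only records of the given canonical SMILES;
#' `dropStructures` removes every record of the given canonical SMILES.
#' Used for leakage-proof validation splits.
#'
#' @param x a [ToxDataset-class].
#' @param smiles character vector of canonical SMILES.
#' @param name optional new dataset label.
#' @return a [ToxDataset-class].
#' @export
keepStructures <- function(x, smiles, name = x@name) {
  rec <- x@records[x@records$canonical_smiles %in% smiles, , drop = FALSE]
  toxDataset(rec, x@structures, name, meta = x@meta)
}

#' @rdname keepStructures
#' @export
dropStructures <- function(x, smiles, name = x@name) {
  keepStructures(x, setdiff(unique(x@records$canonical_smiles), smiles), name)
}

#' Training dataset: union of two databases
#'
#' Pools all records of both datasets and removes duplicates by
#' (canonical structure, dose at five significant digits).
#'
#' @param a,b preprocessed [ToxDataset-class] objects.
#' @param name label for the result.
#' @return a [ToxDataset-class].
#' @export
buildTrainingSet <- function(a, b, name = "training") {
  records <- rbind(a@records, b@records)
  structures <- c(a@structures, b@structures)
  structures <- structures[!duplicated(names(structures))]
  toxDataset(records, structures, name,
             meta = list(sources = c(a@name, b@name)))
}

#' Test dataset: structures occurring in both databases
#'
#' Keeps every record (from either source) of structures present in both
#' datasets, deduplicated as in [buildTrainingSet()].  These compounds
#' have multiple independent studies and anchor both the experimental
#' variability analysis and the model benchmark.
#'
#' @inheritParams buildTrainingSet
#' @return a [ToxDataset-class]; empty (with a warning) if the structure
#'   intersection is empty.
#' @export
buildTestSet <- function(a, b, name = "test") {
  shared <- intersect(unique(a@records$canonical_smiles),
                      unique(b@records$canonical_smiles))
  if (!length(shared))
    warning("no structures occur in both datasets; test set is empty")
  records <- rbind(a@records[a@records$canonical_smiles %in% shared, , drop = FALSE],
                   b@records[b@records$canonical_smiles %in% shared, , drop = FALSE])
  structures <- c(a@structures, b@structures)
  structures <- structures[!duplicated(names(structures))]
  structures <- structures[names(structures) %in% shared]
  toxDataset(records, structures, name,
             meta = list(sources = c(a@name, b@name)))
}
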