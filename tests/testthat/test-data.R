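# Preprocessing: unit conversion, -log10 transform, duplicate removal,
# derived training (union) and test (intersection) datasets.

test_that("unit conversion divides by molecular weight and keeps 5 significant digits", {
  expect_identical(convertUnits(50, 100), 0.5)
  expect_identical(convertUnits(1, 1), 1)
  # 123.456 / 78.9 = 1.5647148... -> 1.5647 at five significant digits
  expect_identical(convertUnits(123.456, 78.9), 1.5647)
  expect_error(convertUnits(-1, 10), class = "ra_config_error")
  expect_error(convertUnits(10, 0), class = "ra_config_error")
})

test_that("negative log10 transform is exact and rejects non-positive doses", {
  expect_identical(negLog10(1), 0)
  expect_identical(negLog10(0.001), 3)
  expect_equal(negLog10(0.5), 0.30103, tolerance = 1e-6)
  expect_error(negLog10(0), class = "ra_config_error")
})

write_table <- function(rows) {
  path <- tempfile(fileext = ".csv")
  writeLines(c("SMILES,LOAEL", rows), path)
  path
}

test_that("reading drops empty values, collects rejects, and deduplicates", {
  path <- write_table(c("CCO,10", "c1ccccc1,5", "CCN,2", "CCC,",
                        "OCC,10", "bad_smiles,3"))
  db <- readLoaelTable(path, "SMILES", "LOAEL", unit = "mg/kg")
  # CCC has an empty value; OCC,10 duplicates CCO,10 after
  # canonicalization; bad_smiles is rejected
  expect_identical(recordCount(db), 3L)
  expect_identical(structureCount(db), 3L)
  expect_identical(db@meta$n_dropped_empty, 1L)
  expect_identical(db@meta$rejects$input_smiles, "bad_smiles")
  expect_true(all(db@records$loael_mmol > 0))
  expect_equal(db@records$loael_neg_log10, -log10(db@records$loael_mmol))
})

test_that("missing columns raise a configuration error", {
  path <- write_table("CCO,10")
  expect_error(readLoaelTable(path, "smiles", "LOAEL"), class = "ra_config_error")
  expect_error(readLoaelTable(path, "SMILES", "loael_mg"), class = "ra_config_error")
})

test_that("values differing beyond 5 significant digits are distinct records", {
  db <- makeToxDataset(list(CCO = c(1, 1)))           # identical -> one record
  expect_identical(recordCount(db), 1L)
  # doses 0.123456 and 0.1234564 mmol/kg both round to 0.12346
  db2 <- makeToxDataset(list(CCO = -log10(c(0.123456, 0.1234564))))
  expect_identical(recordCount(db2), 1L)
  db3 <- makeToxDataset(list(CCO = -log10(c(0.12346, 0.12348))))
  expect_identical(recordCount(db3), 2L)
})

test_that("training set is the deduplicated union, test set the intersection", {
  a <- makeToxDataset(list(CCO = 1, CCC = 2, CCN = 3), "a")
  b <- makeToxDataset(list(CCCC = 1, CCOC = 2, CCCN = 3, CCCCC = 4), "b")
  expect_identical(recordCount(buildTrainingSet(a, b)), 7L)
  expect_warning(te <- buildTestSet(a, b), "empty")
  expect_identical(recordCount(te), 0L)

  a2 <- makeToxDataset(list(CCO = 1, CCC = 2), "a")
  b2 <- makeToxDataset(list(CCC = 2.5, CCN = 3), "b")
  te2 <- buildTestSet(a2, b2)
  expect_identical(datasetSmiles(te2), canonicalizeSmiles("CCC"))
  expect_identical(recordCount(te2), 2L)  # both sources' records of CCC

  # identical record in both sources appears once
  b3 <- makeToxDataset(list(CCC = 2, CCN = 3), "b")
  expect_identical(recordCount(buildTrainingSet(a2, b3)), 3L)
  expect_identical(recordCount(buildTestSet(a2, b3)), 1L)
})

test_that("set identities hold on randomized datasets and dedup is idempotent", {
  pool <- c("CCO", "CCC", "CCN", "CCCC", "CCOC", "c1ccccc1", "c1ccncc1",
            "CC(C)O", "CCCl", "CC=O")
  for (seed in 1:5) {
    set.seed(seed)
    mk <- function(nm) {
      smis <- sample(pool, sample(4:8, 1))
      makeToxDataset(stats::setNames(
        lapply(smis, function(s) round(stats::runif(sample(1:3, 1), 0.5, 3), 3)),
        smis), nm)
    }
    a <- mk("a"); b <- mk("b")
    tr <- buildTrainingSet(a, b)
    expect_setequal(datasetSmiles(tr), union(datasetSmiles(a), datasetSmiles(b)))
    shared <- intersect(datasetSmiles(a), datasetSmiles(b))
    if (length(shared)) {
      te <- buildTestSet(a, b)
      expect_setequal(datasetSmiles(te), shared)
      # every test structure occurs in the training set
      expect_true(all(datasetSmiles(te) %in% datasetSmiles(tr)))
    }
    # dedup idempotence: rebuilding from the deduplicated records changes nothing
    tr2 <- toxDataset(records(tr), structures(tr), tr@name)
    expect_identical(records(tr2), records(tr))
  }
})

test_that("keep/drop structures partition the records", {
  fx <- .fix()
  tr <- fx$training
  some <- datasetSmiles(tr)[1:5]
  kept <- keepStructures(tr, some)
  dropped <- dropStructures(tr, some)
  expect_setequal(datasetSmiles(kept), some)
  expect_identical(recordCount(kept) + recordCount(dropped), recordCount(tr))
  expect_length(intersect(datasetSmiles(kept), datasetSmiles(dropped)), 0L)
})
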