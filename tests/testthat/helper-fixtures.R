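# Shared fixtures, built once per test session.  Everything is generated
# in code; no data files are read.

# default synthetic universe: clustered compounds + singletons, two
# overlapping databases, replicate noise SD 0.3 on the -log10 scale
.fix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gen <- generateSyntheticToxData(syntheticSpec())
      cache <<- list(gen = gen,
                     training = buildTrainingSet(gen$dbA, gen$dbB),
                     test = buildTestSet(gen$dbA, gen$dbB))
    }
    cache
  }
})

# a tiny hand-built ToxDataset: `values` is a named list mapping SMILES
# to -log10(mmol/kg) measurement vectors
makeToxDataset <- function(values, name = "toy") {
  structs <- lapply(names(values), structureFromSmiles)
  can <- vapply(structs, function(s) s@canonicalSmiles, "")
  rec <- do.call(rbind, lapply(seq_along(values), function(i) {
    v <- values[[i]]
    data.frame(input_smiles = names(values)[i], canonical_smiles = can[i],
               loael_mmol = signif(10^(-v), 5),
               loael_neg_log10 = -log10(signif(10^(-v), 5)),
               source = name, original_value = 10^(-v),
               original_unit = "mmol/kg", stringsAsFactors = FALSE)
  }))
  toxDataset(rec, stats::setNames(structs, can), name)
}

# random fingerprint (non-empty subset of an alphabet), for similarity
# property tests
randomFingerprint <- function(alphabet, maxlen = 12) {
  sample(alphabet, sample.int(maxlen, 1))
}
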