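# Synthetic LOAEL data generator.  Emulates the statistical structure of
# the real chronic-toxicity databases: clusters of structurally related
# compounds sharing a scaffold (high within-cluster MolPrint2D
# similarity), a cluster-level structure-activity signal with
# substituent effects, replicate measurements with lognormal noise
# (Gaussian on the -log10 scale), structurally isolated singleton
# compounds, and two overlapping source databases whose intersection
# forms a synthetic test set.

# Scaffold templates: first slot is a fixed per-cluster substituent,
# second slot varies across cluster members.  Cores are large (mostly
# 9-16 heavy atoms) relative to the substituents so that cluster-mates
# stay highly similar (Tanimoto mostly above 0.5) while different
# scaffolds stay dissimilar.
.SCAFFOLDS <- c(
  "c1cc(%s)ccc1CCc1ccccc1%s",
  "c1ccc2cc(%s)ccc2c1CC%s",
  "c1ccc2c(c1)ncc(%s)c2CC%s",
  "C1CC(%s)CCC12CCC(%s)CC2",
  "c1cc(%s)ccc1Oc1ccccc1%s",
  "c1cc(%s)ccc1Cc1ccccc1%s",
  "c1cc(%s)ccc1c1ccccc1%s",
  "c1cc(%s)ccc1S(=O)(=O)Nc1ccccc1%s",
  "c1cc(%s)ccc1C(=O)Oc1ccccc1%s",
  "c1cc(%s)ccc1C(=O)Nc1ccccc1%s",
  "C(%s)CCCCCCCCCCC%s",
  "C1CCC(CC1)C1CCC(%s)CC1%s",
  "c1ccc2c(c1)sc(%s)c2CC%s",
  "c1ccc2c(c1)oc(%s)c2CC%s",
  "c1ccc2c(c1)n(C)c(%s)c2CC%s",
  "C1CCC(CC1)CCC1CCC(%s)CC1%s"
)

.SUBSTITUENTS <- c("C", "CC", "CCC", "C(C)C", "O", "OC", "N", "F", "Cl",
                   "Br", "C#N", "C(=O)O", "CO", "CCO")

# Candidate structurally isolated compounds; each is accepted only after
# verifying Tanimoto < isolation threshold against everything else.
.SINGLETON_POOL <- c(
  "S=C=S", "O=P(O)(O)O", "ClC(Cl)(Cl)Cl", "FC(F)(F)C(F)(F)F", "N#CC#N",
  "OO", "NN", "OB(O)O", "C[Si](C)(C)C", "S1SSSSSSS1", "BrC(Br)Br",
  "O=S(=O)(O)O", "ICI", "OCC#CCO", "O=C(O)C(=O)O"
)

#' Specification of a synthetic LOAEL dataset pair
#'
#' Defaults reflect the conditions the package is exercised under: a
#' replicate noise SD of 0.3 on the -log10 scale (the order of the
#' experimental variability of real chronic-toxicity databases),
#' activities spanning about four orders of magnitude, mostly 1-2
#' replicate measurements per compound and database, roughly a third of
#' the compounds occurring in both databases, and many smallish
#' clusters (16 scaffolds with 5 members each) so that both
#' applicability-domain tiers are populated: well-supported compounds
#' predicted from close neighbours, sparsely supported ones from the
#' lower similarity band.
#'
#' @param nClusters number of structural clusters (each built on its own
#'   scaffold); at most `length(readacross:::.SCAFFOLDS)`.
#' @param clusterSize compounds per cluster; at most
#'   `length(readacross:::.SUBSTITUENTS)`.
#' @param nSingletons structurally isolated compounds.
#' @param overlapFraction probability that a compound occurs in both
#'   databases (these compounds form the synthetic test set).
#' @param noiseSdLog replicate measurement noise SD, -log10 scale.
#' @param activityRange range of cluster base activities,
#'   -log10(mmol/kg bw/day).
#' @param substituentEffectSd SD of the per-substituent activity effects.
#' @param replicateGeomP geometric-distribution parameter for extra
#'   replicates: a compound present in a database gets
#'   `1 + min(rgeom(p), maxReplicates - 1)` measurements there.
#' @param maxReplicates cap on replicates per compound and database.
#' @param isolationThreshold a singleton is accepted only if its maximum
#'   similarity to every other generated structure is below this.
#' @param seed integer seed; the same spec always generates identical
#'   data.
#' @return list of class `SyntheticSpec`.
#' @export
syntheticSpec <- function(nClusters = 16L, clusterSize = 5L, nSingletons = 6L,
                          overlapFraction = 0.3, noiseSdLog = 0.3,
                          activityRange = c(-1, 3), substituentEffectSd = 0.3,
                          replicateGeomP = 0.6, maxReplicates = 4L,
                          isolationThreshold = 0.2, seed = 42L) {
  stopifnot(nClusters >= 0, clusterSize >= 1, nSingletons >= 0,
            noiseSdLog >= 0, overlapFraction >= 0, overlapFraction <= 1,
            length(activityRange) == 2L, activityRange[1] <= activityRange[2])
  if (nClusters > length(.SCAFFOLDS))
    .configError(sprintf("at most %d clusters supported", length(.SCAFFOLDS)))
  if (clusterSize > length(.SUBSTITUENTS))
    .configError(sprintf("at most %d compounds per cluster supported",
                         length(.SUBSTITUENTS)))
  structure(list(nClusters = as.integer(nClusters),
                 clusterSize = as.integer(clusterSize),
                 nSingletons = as.integer(nSingletons),
                 overlapFraction = overlapFraction, noiseSdLog = noiseSdLog,
                 activityRange = activityRange,
                 substituentEffectSd = substituentEffectSd,
                 replicateGeomP = replicateGeomP,
                 maxReplicates = as.integer(maxReplicates),
                 isolationThreshold = isolationThreshold,
                 seed = as.integer(seed)),
            class = "SyntheticSpec")
}

#' Generate a synthetic pair of LOAEL databases
#'
#' Builds the compound set described by the spec, verifies that every
#' generated SMILES parses and that singletons are structurally isolated
#' (maximum Tanimoto similarity to everything else below the isolation
#' threshold; a generation error names the constraint if the candidate
#' pool cannot satisfy it), draws true activities and replicate
#' measurements, and assembles two [ToxDataset-class] objects through the
#' same unit-conversion path used for real data.
#'
#' @param spec a [syntheticSpec()].
#' @return list of class `SyntheticToxData` with elements `dbA`, `dbB`
#'   ([ToxDataset-class]), `truth` (per-compound ground truth: SMILES,
#'   cluster label, true -log10 activity, database membership) and
#'   `spec`.
#' @export
generateSyntheticToxData <- function(spec = syntheticSpec()) {
  stopifnot(inherits(spec, "SyntheticSpec"))
  .withSeed(spec$seed, {
    smiles <- character(); cluster <- character()
    substituent <- character()
    if (spec$nClusters > 0L) {
      scaff <- sample(.SCAFFOLDS, spec$nClusters)
      for (ci in seq_len(spec$nClusters)) {
        s1 <- sample(.SUBSTITUENTS, 1L)
        s2 <- sample(.SUBSTITUENTS, spec$clusterSize)
        smiles <- c(smiles, sprintf(scaff[ci], s1, s2))
        substituent <- c(substituent, s2)
        cluster <- c(cluster, rep(sprintf("cluster%02d", ci), spec$clusterSize))
      }
    }
    structs <- parseStructures(smiles, onError = "collect")
    if (length(attr(structs, "rejects")))
      .configError(paste("synthetic SMILES failed to parse:",
                         paste(attr(structs, "rejects"), collapse = ", ")))
    structs <- unname(structs)

    # singletons: verified structural isolation
    if (spec$nSingletons > 0L) {
      pool <- sample(.SINGLETON_POOL)
      accepted <- 0L
      for (cand in pool) {
        if (accepted >= spec$nSingletons) break
        st <- tryCatch(structureFromSmiles(cand), ra_parse_error = function(e) NULL)
        if (is.null(st)) next
        sims <- vapply(structs, function(x) tanimoto(st, x), numeric(1))
        if (length(sims) && max(sims) >= spec$isolationThreshold) next
        structs <- c(structs, st)
        smiles <- c(smiles, cand)
        cluster <- c(cluster, "singleton")
        accepted <- accepted + 1L
      }
      if (accepted < spec$nSingletons)
        .configError(sprintf(
          "could not find %d singletons with max similarity < %s: pool exhausted",
          spec$nSingletons, format(spec$isolationThreshold)))
    }

    can <- vapply(structs, slot, "", "canonicalSmiles")
    if (anyDuplicated(can))
      .configError("generation produced duplicate canonical structures; use a different seed or smaller clusters")
    n <- length(structs)

    # ground-truth activities: cluster base + a cluster-specific
    # structure-activity slope over the size of the varying substituent.
    # Small structural changes shift the activity little (the similarity
    # principle read-across assumes), the signal is learnable from
    # cluster-mates, and compounds from other clusters carry no
    # transferable signal (their slope and base differ).
    cl_ids <- unique(cluster[cluster != "singleton"])
    base <- stats::runif(length(cl_ids), spec$activityRange[1], spec$activityRange[2])
    names(base) <- cl_ids
    # Per-cluster activity slope per substituent heavy atom, scaled
    # inversely to scaffold size: on a small scaffold one atom changes a
    # larger share of the structure (a bigger similarity decrement), so
    # it shifts the activity more.  This keeps the expected activity
    # difference between two compounds proportional to their structural
    # distance (1 - similarity) across the whole universe, which is what
    # gives the absolute similarity thresholds their meaning.
    sub_ha <- vapply(.SUBSTITUENTS,
                     function(s) structureFromSmiles(s)@heavyAtoms, 0L)
    names(sub_ha) <- .SUBSTITUENTS
    ha_centered <- sub_ha - mean(sub_ha)
    scaffold_ha <- vapply(cl_ids, function(cl) {
      i <- which(cluster == cl)[1]
      st <- structureFromSmiles(smiles[i])
      st@heavyAtoms - sub_ha[[substituent[i]]]
    }, 0L)
    slope <- stats::rnorm(length(cl_ids), 0, spec$substituentEffectSd) *
      8 / scaffold_ha
    names(slope) <- cl_ids
    true <- numeric(n)
    for (i in seq_len(n)) {
      true[i] <- if (cluster[i] == "singleton")
        stats::runif(1, spec$activityRange[1], spec$activityRange[2])
      else base[[cluster[i]]] +
        slope[[cluster[i]]] * ha_centered[[substituent[i]]]
    }

    membership <- sample(c("both", "a", "b"), n, replace = TRUE,
                         prob = c(spec$overlapFraction,
                                  (1 - spec$overlapFraction) / 2,
                                  (1 - spec$overlapFraction) / 2))

    make_records <- function(which_db) {
      idx <- which(membership %in% c("both", which_db))
      rows <- lapply(idx, function(i) {
        k <- 1L + min(stats::rgeom(1L, spec$replicateGeomP),
                      spec$maxReplicates - 1L)
        v <- true[i] + stats::rnorm(k, 0, spec$noiseSdLog)
        mw <- structs[[i]]@molWeight
        mg <- 10^(-v) * mw
        data.frame(input_smiles = smiles[i], canonical_smiles = can[i],
                   loael_mmol = convertUnits(mg, mw),
                   loael_neg_log10 = NA_real_, source = paste0("synthetic-", which_db),
                   original_value = mg, original_unit = "mg/kg",
                   stringsAsFactors = FALSE)
      })
      rec <- do.call(rbind, rows)
      rec$loael_neg_log10 <- negLog10(rec$loael_mmol)
      rec
    }
    rec_a <- make_records("a")
    rec_b <- make_records("b")
    structures <- stats::setNames(structs, can)

    truth <- data.frame(smiles = smiles, canonical_smiles = can,
                        cluster = cluster, true_neg_log10 = true,
                        in_a = membership %in% c("both", "a"),
                        in_b = membership %in% c("both", "b"),
                        stringsAsFactors = FALSE)
    structure(list(
      dbA = toxDataset(rec_a, structures, "synthetic-a"),
      dbB = toxDataset(rec_b, structures, "synthetic-b"),
      truth = truth, spec = spec), class = "SyntheticToxData")
  })
}

#' Write a synthetic dataset pair as CSV files
#'
#' Emits `dbA.csv` and `dbB.csv` in the layout [readLoaelTable()] reads
#' (columns `SMILES`, `LOAEL_mg_kg_bw_day`; one row per measurement) plus
#' `truth.csv` with the ground-truth activities and cluster labels.
#' Output is byte-identical for identical specs.
#'
#' @param spec a [syntheticSpec()].
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of file paths.
#' @export
writeSyntheticCsv <- function(spec, dir) {
  gen <- generateSyntheticToxData(spec)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(dbA = file.path(dir, "dbA.csv"), dbB = file.path(dir, "dbB.csv"),
             truth = file.path(dir, "truth.csv"))
  dump_db <- function(db, path) {
    rec <- db@records
    out <- data.frame(SMILES = rec$input_smiles,
                      LOAEL_mg_kg_bw_day = sprintf("%.8g", rec$original_value),
                      stringsAsFactors = FALSE)
    utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  dump_db(gen$dbA, paths["dbA"])
  dump_db(gen$dbB, paths["dbB"])
  truth <- gen$truth
  truth$true_neg_log10 <- sprintf("%.8g", truth$true_neg_log10)
  utils::write.csv(truth, paths["truth"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}
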