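---
title: "Read-across prediction of chronic LOAELs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Read-across prediction of chronic LOAELs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Chronic oral toxicity studies in rats are slow, expensive and ethically
fraught, and only a small fraction of the chemicals humans are exposed to
through food have ever been tested.  Read-across estimates the lowest
observed adverse effect level (LOAEL) of an untested structure from
experimentally characterized, structurally similar compounds.  This
package automates that workflow as a lazy, local modelling scheme: no
global model is ever trained; for each query a small model is built on
demand from the query's structural neighbourhood, in machine-learning
terms a k-nearest-neighbour method with a local regression model on top.

A distinguishing emphasis is *calibration against experimental
variability*: replicate chronic studies of the same compound disagree
substantially (replicate standard deviations around 0.3 on the -log10
mmol/kg bw/day scale in public databases), and no model predicting from
such data can be more accurate than the data are reproducible.  The
package therefore ships the variability analyses (replicate SDs,
inter-database median correlation) alongside the prediction engine, so
that prediction error is always judged relative to that experimental
baseline.

# Data model and preprocessing

A `ToxDataset` holds one measurement per row (a compound may occur many
times) plus one parsed `Structure` per distinct canonical SMILES.
Preprocessing follows fixed rules:

* doses are converted to mmol/kg bw/day (dividing mg/kg values by the
  average molecular weight computed from the structure) and rounded to
  **five significant digits**, once, at conversion time;
* modelling and validation work on the -log10 of the molar dose, where
  replicate noise is approximately Gaussian (lognormal dose noise);
* records equal in (canonical structure, dose at five significant
  digits) are collapsed: agreement to five digits across independent
  sources is taken as evidence of a shared underlying study, not of
  independent replication.  Duplicate comparisons use the rounded
  decimal representation (`sprintf("%.4e", signif(x, 5))`), never
  floating-point epsilons, so deduplication is deterministic;
* rows with empty dose values are dropped (counted), and unparsable
  SMILES are collected into a rejects report rather than silently lost.

Two derived datasets drive validation: the **training set** (union of
two source databases, deduplicated) and the **test set** (all records of
structures occurring in both databases).  Test-set compounds have at
least two independent measurements, which is what makes them usable both
for estimating experimental variability and for benchmarking
predictions against it.

# Structures and similarity

Structure parsing, canonicalization, aromaticity perception and
molecular weights come from OpenBabel (via ChemmineOB); OpenBabel
canonical SMILES are the identity used for duplicate detection and the
leakage guard.  The fingerprint is MolPrint2D: each heavy atom
contributes one *atom environment* — its own atom type plus the sorted
multisets of atom types at bond distances 1 and 2 (shortest-path
distances over the heavy-atom graph, hydrogens ignored).  Environments
are serialized canonically, so the feature set is invariant to atom
ordering of the input SMILES, and duplicates collapse: a molecule has at
most as many features as heavy atoms (benzene has exactly one).

Atom typing is deliberately simple and swappable: the default scheme is
the element symbol, lower-cased when OpenBabel types the atom as
aromatic (`C` vs `c`).  An alternative scheme using raw OpenBabel
internal atom types (`Car`, `O3`, ...) is available via the `scheme`
argument.  One consequence of the default: atoms OpenBabel types
without an `ar` suffix (e.g. the furan oxygen, typed `O2`) count as
non-aromatic; the convention is applied uniformly to queries and
training structures, so similarities remain coherent.  Because atom
typing conventions differ between toolkits and versions,
fingerprint-level equality with other MolPrint2D implementations is not
guaranteed — only method-level equivalence.

Similarity is the Tanimoto (Jaccard) index on feature *sets*,
|A∩B| / |A∪B|; environment multiplicities do not enter.

# The prediction engine

For a query structure the tiered procedure is:

1. collect all training structures with similarity ≥ **0.5** (training
   records whose canonical SMILES equals the query's are always
   excluded — this leakage guard is hardwired and also protects
   ordinary use against database duplicates);
2. fit a **similarity-weighted random forest** on the neighbours and
   predict.  Success here means a prediction *close to the
   applicability domain*: no warnings;
3. if any step fails, repeat at threshold **0.2**; such predictions
   carry an applicability-domain warning;
4. if the forest cannot be fit at the lower tier either, fall back to
   the similarity-weighted mean of all neighbour measurements
   (additional warning);
5. if there is no neighbour at 0.2 at all, the result is a typed
   no-prediction outcome ("no similar compounds"), not an error.

The two thresholds are the established defaults of this tiered design;
they are configuration (`raControl()`), not quantities to be tuned per
dataset.

## The local model

Each neighbour contributes **one training row per measurement** — a
binary vector over the informative features, the -log10 dose as
response, and the neighbour's similarity as observation weight.
Keeping replicates as separate rows (rather than pre-aggregating to a
median) lets experimental variability propagate into the local model
and its error estimate.  Features constant across the neighbour set
(present in all or none) carry no signal and are removed first; if
nothing remains, the forest cannot be fit and the fallback fires.  At
least two distinct neighbour structures are required to attempt a
forest.

The forest (ranger, 200 trees, single-threaded for reproducibility) has
one tuned hyperparameter, the number of candidate features per split,
selected from the grid floor(√p, p/3, p/2) by bootstrap resampling (25
resamples by default).  **Resampling is grouped by neighbour
structure**: all measurement rows of a compound enter or leave a
resample together.  With row-level resampling, replicates of the same
compound appear on both sides of the split and the out-of-sample
residuals reflect replicate noise only; grouped resampling makes them
measure compound-level prediction error, which is the error a genuinely
new query incurs.  The pooled out-of-sample residuals of the selected
model give the RMSE estimate behind the **95% prediction interval**,
value ± 1.96·RMSE.  For the weighted-mean fallback the RMSE estimate is
the similarity-weighted RMS deviation of the neighbour measurements
about the weighted mean; with a single measurement it is degenerate
(zero width), which is acceptable only because such predictions always
carry warnings.

All randomness (bootstrap, forest) is controlled by an explicit `seed`
argument; identical (query, training, seed) yield identical predictions,
and the caller's RNG stream is left untouched.

# Validation

`evaluateTestSet()` predicts every unique test structure from the
training set and scores against the **median** of the structure's
experimental -log10 values.  The engine's canonical-SMILES exclusion
guarantees no query ever sees its own records; the evaluation re-asserts
this on every neighbour list.  Results are stratified by
applicability-domain tier: *ad-close* (no warnings), *ad-distant*
(warned), *all* (pooled), with failures counted separately.  Reported
per tier: squared Pearson correlation, RMSE, counts, and
prediction-interval coverage (each individual experimental measurement
checked against its compound's interval).

`repeatedKfold()` splits **unique structures** (never individual
measurements) into k folds, predicts each held-out structure from the
remaining folds, and repeats with independent shuffles, reporting mean ±
SD per tier across repeats.  Folds are plain random shuffles; no
activity stratification is applied.  P-values of the correlation tests
are reported but never used as pass/fail logic, and no multiple-testing
correction is applied.

# Experimental variability analyses

* `intraDbVariability()`: per structure with ≥ 2 measurements, the
  sample (n−1) SD of its -log10 values; the report's headline is the
  unweighted mean over compounds (each compound counts once regardless
  of replicate count).  Note the sample SD is biased low at small n
  (E[sd] = c4(n)·σ, c4(2) ≈ 0.80), so with mostly duplicate
  measurements the mean replicate SD underestimates the noise σ; tests
  account for this.
* `interDbCorrelation()`: for shared structures, values identical at
  five significant digits in both databases are excluded (likely the
  same study seen twice); per-database medians of the remainder are
  correlated.
* `compareSdDistributions()`: Welch two-sample t-test on the
  per-compound SD lists.
* `smallCompoundComparison()`: counts structures below a heavy-atom
  cutoff (default 11) and tests the 2×2 table; chi-square without
  continuity correction is the headline p-value, the Yates-corrected
  value is reported alongside.

# The synthetic data generator

Real chronic-toxicity databases cannot be bundled, so the package
generates a synthetic universe with the same statistical anatomy: the
generator (`syntheticSpec()` / `generateSyntheticToxData()`) emits two
overlapping databases of SMILES with replicate measurements, exercising
every pipeline stage including SMILES parsing and unit conversion.

Design, and why:

* **Clusters**: each cluster decorates one scaffold (from a fixed
  internal list of 16 ring/chain systems, cores mostly 9–16 heavy
  atoms) with a fixed first substituent and a varying second one from a
  fixed list of 14 small groups.  Large cores keep cluster-mates mostly
  above 0.5 Tanimoto while different scaffolds stay dissimilar —
  mirroring congeneric series in real databases.
* **Activities**: cluster base drawn uniformly from `activityRange`
  (default −1 to 3, about the span of real chronic LOAELs), plus a
  cluster-specific slope per substituent heavy atom.  The slope is
  scaled inversely to scaffold size: on a small scaffold one atom is a
  larger fraction of the structure (a larger similarity decrement), so
  it shifts activity more.  This keeps the expected activity difference
  between two compounds roughly proportional to their structural
  distance (1 − similarity) across the whole universe — the similarity
  principle that gives the absolute 0.5/0.2 thresholds their meaning.
  Slopes differ between clusters, so neighbours from a foreign cluster
  carry no transferable signal.
* **Noise**: each measurement is the true value plus Gaussian noise on
  the -log10 scale (`noiseSdLog`, default 0.3 — the order of the
  replicate variability observed in real chronic-toxicity databases).
  Replicate counts follow a truncated geometric distribution (most
  compounds 1–2 measurements, few more), and a stated fraction of
  compounds (default 0.3) occurs in both databases, forming the
  synthetic test set.
* **Singletons**: structurally isolated compounds drawn from a pool of
  exotic structures, each accepted only after verifying its maximum
  similarity to everything else is below 0.2; if the pool cannot
  satisfy the constraint a generation error names it.  Singletons are
  the engine's designed failure mode (no similar compounds).

What the generator does **not** emulate: real toxicophore chemistry,
activity cliffs (the synthetic structure–activity surface is smooth
within clusters), heteroscedastic study noise (dose spacing, route of
administration), and the long-tailed structural diversity of regulatory
databases.  Passing tests on this universe therefore demonstrate that
the machinery is correct and calibrated under its stated assumptions —
not that real-world accuracy will match.

# Numerical and design choices

* Five-significant-digit rounding happens once, at unit conversion;
  all later equality tests compare rounded decimal strings.
* Feature strings and neighbour tie-breaks sort with radix order
  (locale-independent); neighbours are ordered by descending
  similarity, ties broken by canonical SMILES, so output is
  platform-stable.
* Average (not monoisotopic) atomic masses are used for mg→mmol
  conversion.
* Seeds: every stochastic routine takes an explicit integer seed;
  internal derived seeds are small offsets of it.
* Test and example problem sizes (16 clusters × 5 compounds + 6
  singletons; 3 repeats of 10-fold cross-validation) are chosen so the
  full suite runs in minutes on one core, both applicability-domain
  tiers are populated, and ≥ 50 multi-measured compounds exist where
  variability recovery is asserted.

# Known limitations

* Exact numeric agreement with other MolPrint2D/random-forest
  implementations is not claimed: atom-typing schemes, forest defaults
  and bootstrap details differ between toolkits, and the published
  analyses of the real databases specify neither completely.
* The weighted-mean fallback's interval is degenerate for a single
  neighbour measurement (always warned).
* The applicability-domain tiers are binary (warnings present/absent);
  the quantitative similarity information in the neighbour table is
  reported but not further summarized.
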