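# readacross

Automated read-across prediction of chronic oral rat toxicity (LOAEL)
in R, with the experimental variability of the underlying animal
studies as the benchmark for prediction quality.

## The problem

Most chemicals that can reach the food chain have never been tested in
a chronic animal study, yet risk assessment needs a quantitative
toxicity value — typically the lowest observed adverse effect level
(LOAEL, here in mmol/kg body weight/day) — to compare against exposure.
Read-across fills the gap: the LOAEL of an untested structure is
estimated from experimentally characterized, structurally similar
compounds.  Because replicate chronic studies of the *same* compound
commonly disagree by a factor of two or more, a sensible question is
not "is the prediction exact?" but "is the prediction error within the
reproducibility of the experiment?" — and this package computes both
sides of that comparison.

## The method

For a query structure *Q* and a training database of (structure, LOAEL)
records:

1. **Fingerprint** every structure with MolPrint2D atom environments:
   each heavy atom is encoded as its atom type plus the sorted atom-type
   multisets at bond distances 1 and 2.  Chemical similarity is the
   Tanimoto index on the environment sets,
   `sim(A, B) = |A ∩ B| / |A ∪ B|`.
2. **Collect neighbours** with `sim ≥ 0.5` (records whose canonical
   SMILES equals the query's are always excluded — the hard-wired
   leakage guard).
3. **Fit a local weighted random forest**: one training row per
   neighbour measurement (binary atom-environment descriptors,
   −log10 LOAEL response, neighbour similarity as observation weight);
   the features-per-split parameter is tuned by bootstrap resampling
   grouped by neighbour structure, and the pooled out-of-sample
   residuals give the model RMSE.  The **95% prediction interval** is
   value ± 1.96·RMSE.
4. **Tiered applicability domain**: if any step fails the procedure is
   repeated at `sim ≥ 0.2` and the prediction is flagged; if the forest
   fails there too, the similarity-weighted mean of the neighbour
   measurements is used (also flagged).  With no neighbour at 0.2 the
   result is a typed no-prediction outcome.  Predictions without
   warnings are *close* to the applicability domain; flagged ones are
   *distant* and deserve manual inspection of the neighbour table.

Validation is leakage-proof by construction (`evaluateTestSet()`,
`repeatedKfold()` with structure-level folds), and the variability
module (`intraDbVariability()`, `interDbCorrelation()`) quantifies the
experimental baseline those errors should be compared with.

## Worked example

```r
library(readacross)

# a synthetic pair of LOAEL databases with realistic structure:
# scaffold clusters, replicate noise SD 0.3 (-log10 scale), singletons
gen <- generateSyntheticToxData(syntheticSpec(seed = 42))
training <- buildTrainingSet(gen$dbA, gen$dbB)
training
#> ToxDataset: training
#>    151 LOAEL records / 86 unique structures
#>    35 structures with multiple measurements

p <- predictLoael("c1cc(CC)ccc1CCc1ccccc1CO", training, seed = 1)
p
#> LoaelPrediction for CCc1ccc(cc1)CCc1ccccc1CO
#>   -log10(mmol/kg bw/day): 0.252  [-0.297, 0.802]
#>   mg/kg bw/day:           134.4  [37.96, 475.9]
#>   method: local-rf  similarity threshold: 0.5  neighbours: 3
#>   within applicability domain (no warnings)
```

Reading the output: the point estimate is 0.25 on the −log10(mmol/kg
bw/day) scale (about 134 mg/kg bw/day for this compound's molecular
weight), the 95% prediction interval spans roughly 38–476 mg/kg bw/day
— about one order of magnitude, which is the honest precision of a
read-across from three neighbours carrying replicate noise — and the
prediction used the strict 0.5 similarity tier, so no
applicability-domain warning is attached.  `p@neighbors` lists the
neighbours, their similarities and their measurements for manual
inspection.

A command-line front end with the same functionality (predict,
validate, variability, fixtures) is in `inst/cli/readacross.R`.

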