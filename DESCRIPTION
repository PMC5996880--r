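Package: readacross
Title: Automated Read-Across Prediction of Chronic Oral Toxicity (LOAEL)
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Lazy, local structure-activity modelling of chronic oral rat
    lowest-observed-adverse-effect levels (LOAEL).  For a query structure the
    engine searches a training database for structural neighbours using
    MolPrint2D atom-environment fingerprints and Tanimoto similarity, fits a
    similarity-weighted local random-forest regression on the neighbours'
    replicate measurements, and reports a point prediction with a 95%
    prediction interval and applicability-domain warnings from a tiered
    similarity-threshold procedure (0.5, then 0.2, then a similarity-weighted
    mean fallback).  Includes leakage-proof test-set evaluation and repeated
    structure-level k-fold cross-validation, experimental-variability
    analyses (replicate standard deviations, inter-database median
    correlation, dataset-composition tests) that benchmark prediction error
    against the reproducibility of the animal studies themselves, and a
    synthetic data generator producing clustered SMILES datasets with
    controlled structure-activity signal and replicate noise.
License: GPL-3
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    ChemmineOB,
    ranger
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
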