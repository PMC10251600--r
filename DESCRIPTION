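Package: liabprof
Title: Ligand-Based Off-Target Liability Profiling with Tuned Tree Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale QSAR pipeline for small-molecule safety pharmacology:
    curation of heterogeneous structure-activity records into QSAR-ready
    datasets (salt stripping, neutralization, pACTIVITY normalization, median
    de-duplication), a 2059-feature encoding (11 physicochemical descriptors
    plus radius-6 extended-connectivity and feature-invariant circular
    fingerprints folded to 1024 bits each), stratified and alternative
    train/test splitting, multi-linear, random-forest and gradient-boosting
    regression with hybrid Latin-hypercube plus genetic-algorithm
    hyperparameter tuning, OECD-style internal and external validation
    (cross-validation, bootstrap, y-randomization), enrichment-factor and AUC
    screening-power analysis, Tanimoto applicability-domain assessment, and
    aggregation of per-target predictions into seven mechanistic liability
    scores. A seeded synthetic structure-activity generator with a packaged
    fragment grammar makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    ChemmineR,
    ChemmineOB,
    methods,
    stats,
    utils,
    xgboost,
    ranger,
    lhs,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
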