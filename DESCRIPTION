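Package: breathVOC
Title: Exhaled-Breath GC-MS Volatile Organic Compound Screening and
    Classification
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for exhaled-breath
    GC-MS studies of ventilated intensive-care patients: aggregation of
    aligned ion fragments into per-compound (VOC) intensities by
    retention-time windowing and co-elution-aware correlation grouping,
    univariate screening by Wilcoxon rank-sum p-value and AUROC with a
    dual selection gate, label-permutation false-discovery assessment,
    principal component analysis, a NIPALS PLS-DA classifier with
    per-sample predicted probabilities, leave-one-out cross-validation
    with in-fold feature selection, and probability extrapolation to
    intermediate clinical groups. Includes a seeded synthetic-data
    generator emulating the statistical structure of such cohorts so
    the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    IRanges,
    SummarizedExperiment,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: Metabolomics, MassSpectrometry, Classification, Software
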