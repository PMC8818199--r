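Package: qmspPanel
Title: Evaluation of Urinary DNA Methylation Marker Panels from qMSP Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for diagnostic evaluation of urinary DNA methylation
    marker panels measured by quantitative methylation-specific PCR (qMSP).
    Normalizes raw quantification cycles to ACTB-referenced methylation
    ratios with reference-gene quality control, performs per-marker
    rank-based inference and ROC analysis, derives Youden-index thresholds
    for a believe-the-positive two-marker panel (default GHSR/MAL),
    estimates diagnostic performance with exact binomial confidence
    intervals, validates it by leave-one-out cross-validation, subgroup and
    gender-stratified analyses, and sizes diagnostic-accuracy studies from
    the Hanley-McNeil variance of the AUC. A synthetic cohort generator
    emulating a case-control bladder cancer study supports testing and
    power exploration when patient-level data are unavailable.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
biocViews: DNAMethylation, Classification, Epigenetics, DiagnosticQuantitative
RoxygenNote: 7.3.3
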