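Package: breathVOC
Title: Breath-Phase-Resolved VOC Profiling from PTR-TOF-MS Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of time-resolved proton-transfer-reaction
    time-of-flight mass spectrometry (PTR-TOF-MS) recordings of exhaled
    breath: mass-axis recalibration against PerMaSCal reference ions,
    extracted-ion-current tracing, water-adduct/tracer-VOC breath-phase
    segmentation with quality control, composite-spectrum peak detection and
    cross-sample alignment into an internal-standard-normalized feature
    matrix, chemical annotation (library matching, exhaustive elemental
    composition enumeration, isotopologue flagging), cohort statistics with a
    normality-routed test decision tree, and resampling-consensus feature
    selection with cross-validated gradient-boosted classifiers for airway
    disease diagnosis and bronchodilator responsiveness. Includes a synthetic
    recording and cohort generator that provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    signal,
    xgboost,
    pROC,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
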