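Package: trspredict
Title: Multimodal Prediction of Treatment-Resistant Psychosis from
    Clinical, Morphometric and Inter-Subject Correlation Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for predicting treatment resistance in first-episode
    psychosis cohorts from multimodal data. Implements per-subject
    inter-subject correlation (ISC) maps of naturalistic fMRI time series
    against an independent reference group, atlas-based region pooling of
    ISC and voxel-based morphometry (VBM) maps, leakage-safe clinical
    preprocessing, a sparse per-modality sigmoid neural network with
    layer-wise relevance propagation, a linear support-vector-machine
    baseline, randomized-pair cross-validation with ensemble hard voting,
    and permutation and bootstrap inference on classifier accuracy. A
    synthetic-cohort generator with configurable planted group effects
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    e1071,
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
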