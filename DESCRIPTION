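Package: copdfuse
Title: Multi-Modal Fusion of CT Volumes and Clinical Indicators for COPD Staging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies chronic obstructive pulmonary disease (COPD) severity
    stage from paired physiological/biochemical (PB) indicator tables and 3D
    lung CT volumes. The PB branch builds a Pearson-correlation feature graph
    and processes it with mean-aggregation graph neural network layers,
    TopK graph pooling and a mean/max multi-scale readout; the CT branch is a
    3D residual convolutional network over Hounsfield-unit normalized volumes;
    the two 64-dimensional modality vectors are combined by low-rank
    multi-modal fusion (LMF) followed by cross-modal and self-attention
    transformer blocks and a joint classification head, trained end to end
    with cross-entropy. Includes tabular preprocessing (3-sigma outlier
    screening, class-restricted KNN imputation, least-squares resolution of
    repeated measurements), stratified splitting and cross-validation,
    confusion-matrix metrics and AUC, pooling-plus-ablation indicator ranking
    with group statistics, and a synthetic paired-modality data generator for
    benchmarking every stage without access to hospital data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
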