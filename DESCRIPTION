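Package: neuroslice
Title: Multi-Slice MRI Data Generation and 3D-CNN Classification for
    Case-Control Neuroimaging Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: A toolkit for building subject-level image classification
    pipelines from raw structural (3D) and functional (4D) MRI volumes.
    Provides NIfTI input/output with PNG slice export, a synthetic
    brain-phantom cohort generator with nested tissue compartments and a
    class-dependent temporal signal, fuzzy c-means tissue-mean intensity
    normalization, leakage-free subject-level train/test splitting,
    multi-slice extraction along the axial, coronal and sagittal planes,
    temporal-window selection and mean-image computation for 4D series, a
    compact 3D convolutional neural network classifier trained with Adam
    on binary cross-entropy, a transfer-learning head for pluggable
    feature-extractor backbones, and evaluation metrics (accuracy, F1,
    cross-entropy) with report generation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    png,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    e1071,
    EBImage,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
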