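Package: liverseg
Title: Two-Stage 3D U-Net Segmentation of Liver and Liver Tumors from CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Cascaded coarse-to-fine segmentation of the liver and liver
    tumors from abdominal CT volumes. Implements a 3D U-Net backbone with
    structurally re-parameterizable residual blocks (parallel convolution
    branches merged into a single equivalent kernel for deployment) and
    slice-wise multi-scale strip-convolution attention, trained with hybrid
    Dice/Tversky/cross-entropy losses under a decaying deep-supervision
    schedule. Includes Hounsfield-unit preprocessing with invertible
    geometry, sliding-window cascaded inference with largest-component
    post-processing, a surface-distance evaluation suite (Dice, average
    symmetric surface distance, relative volume difference, precision,
    recall, lesion Feret diameters), and a synthetic CT phantom generator
    so every stage is testable without external data. Networks, gradients
    and the optimizer are implemented natively on dense arrays with
    compiled convolution kernels.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
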