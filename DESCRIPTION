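Package: vesselseg
Title: Unsupervised Cerebrovascular Segmentation with Hidden Markov Random
    Fields and Encoder-Decoder Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Unsupervised segmentation of cerebral vasculature in
    skull-stripped, bias-corrected time-of-flight magnetic resonance
    angiography (TOF-MRA) volumes. A Gaussian hidden Markov random field
    (HMRF) model optimized by expectation-maximization with iterated
    conditional modes produces three-class pseudo-labels (background, brain
    tissue, vessel) without manual annotation; the pseudo-labels train small
    encoder-decoder networks (a three-axis 2D SegNet ensemble and a
    patch-based 3D U-Net) whose soft-max probability maps segment vessels in
    unseen volumes. Includes a synthetic vascular phantom generator with
    known ground truth, maximum-intensity-projection (MIP) evaluation
    metrics (accuracy, sensitivity, specificity, precision, Dice similarity
    coefficient), NIfTI input/output, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    EBImage,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
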