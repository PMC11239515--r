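Package: SpineMoCo
Title: Unsupervised Slicewise Deformable Motion Correction for Spinal Cord fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Retrospective motion correction for axial spinal cord functional
    MRI time series. Implements a centerline-realignment preprocessing step
    (intensity-centroid tracking, interquartile-range outlier fences, cubic
    B-spline repair, translational realignment), an unsupervised
    encoder-decoder convolutional network that predicts dense in-plane
    displacement fields slice by slice, a differentiable bilinear warper,
    mean-squared-error and locally windowed normalized cross-correlation
    similarity losses with a displacement-gradient smoothness penalty, and
    temporal SNR, DVARS and Pearson-correlation quality-control metrics.
    Includes a synthetic spinal-cord phantom generator with known ground-truth
    motion so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    splines,
    Rcpp,
    RNifti,
    jsonlite,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
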