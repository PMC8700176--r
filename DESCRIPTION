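Package: prcnet
Title: Convolutional Positron Range Correction for Ga-68 Preclinical PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and correction of positron-range blur in Ga-68
    small-animal PET. Provides voxelized digital phantoms (a procedural
    brain surrogate and NEMA-style rod, sphere and hot-rod phantoms), an
    image-domain acquisition simulator that produces paired Ga-68
    (range-blurred) and back-to-back 511-keV gamma (range-free) volumes
    with Poisson counting noise, patch-based training-set construction,
    three fully convolutional deblurring networks (a 3-layer
    super-resolution network, a 4-layer valid-convolution network and its
    deeply supervised, densely connected variant) trained with momentum
    SGD, and NEMA NU-4 style image-quality metrics (RMSE, PSNR, recovery
    coefficients, spill-over ratios and their coefficients of variation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    tibble,
    ggplot2,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
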