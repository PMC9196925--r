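Package: maflim
Title: Multispectral Autofluorescence Lifetime Imaging Analysis of Skin Lesions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of multispectral time-resolved
    autofluorescence (maFLIM) dermoscopy images. Provides a synthetic-data
    generator for patient-grouped lesion cohorts (per-pixel biexponential
    decays convolved with an instrument response function), pixel- and
    image-level preprocessing (offset subtraction, spatial averaging,
    SNR/saturation masking, channel concatenation, two-region K-means
    clustering), time-domain feature extraction by nonlinear least-squares
    iterative reconvolution, fitting-free frequency-domain phasor feature
    extraction at the first nine harmonics, and benign/malignant lesion
    classification with quadratic discriminant analysis, sequential forward
    feature selection inside leave-one-patient-out cross-validation, and
    weighted-posterior ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    MASS,
    pROC,
    jsonlite,
    minpack.lm
Config/testthat/edition: 3
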