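Package: adcontinuum
Title: Stage-Dependent Multimodal Brain-Memory Associations Along the
    Alzheimer's Disease Continuum
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Models how the association between multimodal brain measures
    (free-water fraction, free-water-corrected fractional anisotropy, grey
    matter volumes, default-mode-network functional connectivity) and memory
    impairment varies with dementia severity on the Alzheimer's disease
    continuum.  Provides a sparse varying coefficient regression with
    B-spline coefficient functions and a functional group-LASSO penalty,
    bi-tensor free-water elimination fitting for single-shell diffusion MRI,
    permutation-based mass-univariate screening (max-statistic, TFCE and
    cluster-extent familywise error control), bootstrap stability bands and
    permutation specificity checks, plus seeded synthetic-cohort generators
    so the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    grDevices,
    jsonlite,
    Rcpp,
    splines,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
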