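Package: pinholetomo
Title: Pinhole SPECT System-Matrix Modelling and Iterative Reconstruction
Version: 0.1.0
Authors@R: person("pkg", "maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: System-matrix modelling for single- and multi-pinhole SPECT with
    detector-space point-spread-function (PSF) convolution, depth-of-interaction
    (DOI) crystal subdivision, simple and full attenuation correction, and image
    masking. Provides matched sparse forward/back projectors (in-memory or
    per-angle), iterative reconstruction (MLEM, OSEM, ordered-subsets one-step-late
    with median root prior, ordered-subsets separable paraboloidal surrogates with
    quadratic prior), digital phantoms with Poisson acquisition simulation,
    NEMA-style figures of merit (contrast-to-noise ratio, coefficient of
    variation, uniformity, FWHM resolution), Interfile-dialect I/O, and a
    command-line interface.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
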