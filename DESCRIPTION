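Package: ckics
Title: Confinement k-Space Image Correlation Spectroscopy
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis toolkit for confinement k-space image
    correlation spectroscopy (c-kICS). Simulates two-dimensional Brownian
    diffusion of membrane particles partitioning in and out of static circular
    microdomains, renders fluorescence microscopy image time series with a
    Gaussian point-spread function and additive background noise, computes
    circularly averaged k-space temporal correlation functions, and fits one-
    and two-component Gaussian decay models to extract confinement parameters:
    macro- and micro-scale diffusion coefficients, the micro-component plateau
    and its effective confinement radius, amplitude saturations, and the
    partition coefficient linking free and effective diffusion.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    minpack.lm,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'ckics-package.R'
    'conditions.R'
    'AllClasses.R'
    'AllGenerics.R'
    'sim-config.R'
    'sim-engine.R'
    'image-synth.R'
    'kics-core.R'
    'confinement-fit.R'
    'pipeline.R'
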