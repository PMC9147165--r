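Package: oilspec
Title: Chemometric Calibration of Vegetable Oil Quality from FT-IR Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for multivariate calibration of
    vegetable-oil quality indices (fatty-acid composition, iodine value and
    other pharmacopoeial values) from Fourier-transform infrared spectra.
    Implements spectral preprocessing (normalization, standard normal
    variate, finite-difference derivatives, single-level Haar wavelet
    compression, and a random-data control), variable selection by standard
    deviation, correlation or chemically informative windows, NIPALS partial
    least squares regression with leave-one-sample-out selection of latent
    factors, and an exhaustive model grid over acquisition and processing
    parameters with report tables of model quality. Includes a synthetic
    spectra generator based on Beer-Lambert mixing of Gaussian component
    bands so that every stage is testable without measured spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
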