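Package: sersquant
Title: Robust Concentration Prediction from SERS Spectra with a
    GA-Initialised Separable Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative surface-enhanced Raman spectroscopy (SERS)
    chemometrics for drug concentration prediction. Implements airPLS
    baseline correction with a sparse Whittaker smoother, characteristic
    peak-window selection, a robust kernel-Huber loss (Huber loss with
    Gaussian-kernel sample weighting), a residual depthwise-separable 1D
    convolutional regression network trained by hand-written
    backpropagation, an adaptive genetic algorithm that searches the
    network's initial weights, and the standard chemometric evaluation
    suite (R2, MedAE, MAPE, RMSE, RMSEC, RPD). Ships a seeded synthetic
    SERS spectrum generator so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    tibble
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
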