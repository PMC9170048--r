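Package: behavdim
Title: Dimensionality of Behavioral Time Series from Predictive Information
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Operational estimates of the dimensionality of behavior: the
    minimum number of features of the past of a scalar behavioral time
    series needed to capture all predictive information about its future.
    Provides exact simulators for Ornstein-Uhlenbeck, latent linear-Gaussian
    and power-law-correlated Gaussian processes; windowed covariance and
    inverse-kernel construction with past-future block spectra and effective
    rank; transfer-matrix analysis and pairwise maximum-entropy fitting of
    two-state (Ising) behavioral sequences; and Gaussian predictive
    information, its scaling with window size, and saturation-based
    dimensionality via canonical correlations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
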