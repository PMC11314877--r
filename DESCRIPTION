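Package: spadspec
Title: SPAD Estimation from Canopy Hyperspectral Reflectance via
    Fractional-Order Differentiation and Successive Projections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chemometric pipeline for estimating leaf chlorophyll (SPAD)
    from canopy hyperspectral reflectance under CO2 microleakage stress:
    quality control and five-point weighted smoothing,
    Grunwald-Letnikov fractional-order spectral differentiation over a
    grid of orders, successive-projections-algorithm (SPA) band
    selection, multiple linear regression and partial least squares
    calibration, per-order accuracy sweeps with optimal-order selection,
    and spectral-feature extraction (green peak, red valley, red edge).
    Includes a synthetic canopy-spectra generator reproducing the
    qualitative physics the method relies on, so the full pipeline is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
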