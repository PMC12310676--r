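Package: canopysat
Title: Satellite Band Simulation and Nitrogen Estimation from Canopy Hyperspectra
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates multispectral satellite observations (Landsat-8,
    Sentinel-2, GF-6) from 1-nm canopy hyperspectral reflectance by
    spectral-response-function convolution, and evaluates how well the
    simulated bands recover canopy nitrogen concentration across apple
    phenological stages. Includes a seeded synthetic canopy spectral
    generator with a known nitrogen-to-spectrum coupling,
    Savitzky-Golay smoothing, normalized-difference band-pair screening
    by Pearson correlation, a from-scratch NIPALS partial least squares
    regression for band-combination ablations, and epsilon-SVR plus
    single-hidden-layer neural network estimators evaluated with
    R-squared and RMSE on paired 60/40 train/validation splits.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    quadprog,
    readr,
    stats,
    tools,
    truncnorm,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
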