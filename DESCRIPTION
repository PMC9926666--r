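Package: eemferm
Title: 2D-Fluorescence Chemometrics for Microtiter-Plate Fermentation Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for monitoring microtiter-plate batch cultivations from
    time-resolved excitation-emission matrix (EEM) fluorescence spectra.
    Implements the full chemometric chain: spectral preprocessing (emission
    windowing, moving-average smoothing, downsampling, scattered-light
    masking, referencing to the first spectrum), temporal alignment of sparse
    offline samples by linear interpolation, SIMPLS partial least squares
    regression of glycerol, cell dry weight and pH, latent-variable selection
    by a dual-RMSE divergence criterion, PCA diagnostics, and oxygen transfer
    rate estimation from headspace pO2 traces (Stern-Volmer quenching plus a
    stop-flow headspace balance). A mechanistic synthetic-data generator of
    secondary-substrate-limited batch cultures and their EEM spectra makes
    every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    deSolve,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
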