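Package: chemocal
Title: Multivariate Spectral Calibration with D-Optimal Validation Design
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end chemometric workflow for simultaneous quantification
    of spectrally overlapped analytes from UV absorbance spectra. Provides
    multilevel multifactor (Brereton) calibration designs, D-optimal
    validation-set selection by Fedorov row exchange, a Beer-Lambert
    bilinear spectra simulator, three calibration engines (classical least
    squares with intercept and moving-window smoothing, NIPALS partial
    least squares with cross-validated latent-variable selection, and
    constrained multivariate curve resolution by alternating least squares
    with evolving factor analysis initialization), a full figures-of-merit
    suite (RMSEC, RMSECV, RMSEP, bias, SEC, RRMSEP, BCRMSEP, recovery, net
    analyte signal detection limits, bias t-test), and model diagnostics
    (elliptical joint confidence regions, cosine similarity, rotational
    ambiguity feasible bands, local rank maps).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
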