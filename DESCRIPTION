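Package: nirtraj
Title: Processing Trajectories for Near-Infrared Multivariate Calibration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Builds and compares quantitative near-infrared (NIR)
    calibration models by exhaustive enumeration of modeling paths
    ("processing trajectories"). Provides NIPALS PLS1 regression with
    cross-validation, bootstrap-aggregated (bagging) PLS ensembles,
    Savitzky-Golay smoothing and derivative pretreatments, interval-based
    variable selection (iPLS, BiPLS, SiPLS), Kennard-Stone sample set
    partitioning, RMSEP/RPD model evaluation with RPD-band classification,
    a one-factor-at-a-time stepwise optimizer for comparison, and a
    seeded generator of synthetic Beer-Lambert mixture spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    signal,
    jsonlite,
    yaml,
    optparse
Config/testthat/edition: 3
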