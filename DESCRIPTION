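Package: paleoniche
Title: Time-Aggregated Species Distribution Models for Detecting Niche
    Change from Radiocarbon-Dated Occurrences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits presence/background generalized additive models to
    radiocarbon-dated species occurrences aggregated across paleoclimate
    time slices, and tests whether the realized niche changed through time
    by comparing a constant-niche model (environmental smooths only)
    against a changing-niche model (environment-by-time tensor-product
    smooths) with AIC across repeated background draws. Includes a
    synthetic paleoclimate and occurrence generator, time-matched
    background sampling, the continuous Boyce index for presence-only
    evaluation, deviance-partition variable importance, model ensembling,
    minimum-predicted-area binarization, and per-period range maps, plus
    diagnostics (collinearity and concurvity screens, simulation-based
    quantile residual checks, Moran's I on residuals).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    mgcv,
    geosphere,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
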