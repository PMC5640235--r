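Package: campimetr
Title: Flat-Screen Visual Field Examination Engine
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A headless engine for campimetric (flat-screen) visual field
    examination. Provides display luminance calibration (HSB brightness to
    cd/m2 via a quadratic photometer fit with chi-squared goodness of fit),
    visual-angle geometry for tangent screens including sphericity
    correction, an adaptive bracketing staircase for per-location luminance
    threshold estimation, Heijl-Krakau style blind-spot and fixation-point
    fixation monitoring, decibel sensitivity maps with test-retest
    aggregation and subtraction comparison, plain-text registries and
    settings templates, and a configurable simulated observer so that the
    full closed examination loop can be exercised and validated without a
    display or a patient.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ggplot2,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
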