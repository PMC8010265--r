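Package: drydownr
Title: Dry-Down Phenotyping of Drought Response from Daily Pot Weights
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for glasshouse dry-down drought phenotyping experiments in
    which potted plants are weighed daily as the soil dries. Converts raw pot
    weights into daily transpiration, transpiration ratio (TR), normalized
    transpiration rate (NTR) and the fraction of transpirable soil water
    (FTSW); estimates the critical FTSW threshold (FTSWc) at which stomata
    begin to close via two-segment plateau regression with bootstrap
    confidence intervals, and fits the logistic NTR-FTSW response curve.
    Includes a knotted linear-spline trend analysis of thresholds across
    decades of cultivar release, vapor pressure deficit calculations, a
    synthetic dry-down experiment simulator with known ground truth for
    parameter-recovery testing, and a packaged reference table of 80 white
    clover (Trifolium repens L.) cultivars.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
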