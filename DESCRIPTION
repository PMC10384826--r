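Package: ctlgels
Title: Models of CTL-Mediated Control of Tumor Cells in Collagen-Fibrin Gels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Growth and killing models for cytotoxic T lymphocyte (CTL) control
    of B16 melanoma cells in collagen-fibrin gel assays. Fits a family of
    exponential-growth/killing models (mass-action, saturating, power-law, and
    suppression-in-growth with mass-action killing) to log-transformed gel
    cell-count data by least squares, compares models by AIC and Akaike
    weights, derives CTL-efficacy metrics (time to 90% kill, control CTL
    concentration), estimates net growth and CTL-attributable death rates, and
    provides a simulation-based power analysis for choosing experimental
    designs via model-recovery Akaike-weight matrices and a determinant
    difference statistic with null-distribution and permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    deSolve,
    lhs,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
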