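Package: raschdash
Title: Rasch Partial Credit Calibration and Interval Rescoring of QuickDASH Subscales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for Rasch measurement analysis of short patient-reported
    outcome scales, developed around the QuickDASH task (items 1-6) and
    symptom (items 9-11) subscales in Dupuytren disease and carpal tunnel
    syndrome. Provides Mokken scalability screening (Loevinger H), marginal
    maximum likelihood estimation of the partial credit model, Andrich
    threshold diagnostics with automatic collapsing of disordered response
    categories, item and scale fit statistics (infit and outfit mean squares,
    sum-score chi-square, Yen's Q3, limited-information scale indices,
    Cronbach alpha), expected a posteriori scoring, and Lord-Wingersky
    sum-score crosswalks that convert ordinal raw sums to interval-level
    0-100 scores. Ships the published condition-specific QuickDASH
    conversion tables and a partial-credit response simulator for testing
    every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    KernSmooth,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
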