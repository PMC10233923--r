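Package: hmiol
Title: Machine-Learning Intraocular Lens Power Calculation for Highly Myopic Eyes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for intraocular lens (IOL) power calculation in highly
    myopic eyes (axial length >= 26 mm). Implements the SRK/T and Haigis
    thin-lens vergence formulas (forward refraction prediction, closed-form
    inversion for a target refraction, and lens-constant conversions), a
    four-sub-model weighted ensemble (gradient-boosted trees and kernel
    support vector regression on two feature sets) that predicts
    postoperative spherical equivalent, inverse IOL-power selection for a
    target refraction, a formula-benchmarking battery (prediction-error
    summaries, accuracy bands, cumulative error curves, formula performance
    index, Friedman, Cochran's Q, log-rank and Pearson comparisons), and a
    seeded synthetic-cohort generator with a known ground-truth refraction
    model for end-to-end testing without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    e1071,
    xgboost,
    survival
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr
Config/testthat/edition: 3
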