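Package: maxsuit
Title: Presence-Only Maximum-Entropy Suitability Modelling and
    Climate-Scenario Change Accounting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits presence-only maximum-entropy species distribution
    models (linear, quadratic, product, hinge and threshold features,
    L1 regularization, cloglog suitability output) and surrounds the
    fitter with the tools an environmental-suitability study needs:
    ESRI ASCII raster stacks on a shared analysis grid, occurrence
    deduplication to one record per cell, slope derivation, matrix
    correlation (RM) variable subset selection, percent contribution,
    permutation importance and jackknife gain diagnostics, backward
    elimination under an AUC floor, projection onto past and future
    climate-scenario stacks, and threshold-free contraction/expansion
    area accounting by current-suitability class. A synthetic-data
    module generates correlated environmental fields, scenario shifts
    and presence samples from a known niche so the whole pipeline is
    testable against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    knitr
Config/testthat/edition: 3
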