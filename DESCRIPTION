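Package: tilescreen
Title: Design and Analysis of CRISPR Tiling Screens for Function-Based
    Drug Discovery
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for designing and analysing pooled CRISPR tiling
    screens. Computes the cell numbers, effective virion amounts and
    transduction volumes required to cover a guide library with a skewed
    abundance distribution, using a weighted coupon-collector bound and
    Poisson transduction statistics. Scores guide count tables into
    dropout (fitness) and function (sorting) log2 fold changes, maps
    guides onto protein residues at the predicted Cas9 cut site,
    corrects guide-dependent efficiency bias with out-of-fold
    gradient-boosted regression, and extracts functional sequence
    intervals by full width at half maximum. Includes classifier-based
    flow-cytometry gating at a user-set false-discovery rate, a
    pluggable compound-protein scorer with deletion-scan stability
    analysis and rank-context comparison, a stacked blood-brain-barrier
    logBB predictor, and seeded synthetic-data generators for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    S4Vectors,
    SummarizedExperiment,
    MASS,
    xgboost,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
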