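Package: refstab
Title: Reference Gene Stability Analysis for RT-qPCR Normalization
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Selects stable reference (housekeeping) genes for RT-qPCR
    normalization from a matrix of quantification-cycle (Cq) values.
    Implements the four standard expression-stability algorithms - geNorm
    (stepwise M-value ranking and pairwise-variation analysis for the
    optimal number of reference genes), NormFinder (model-based intra- and
    inter-group variance decomposition), BestKeeper (descriptive dispersion
    statistics and index correlations on raw Cq), and the comparative
    delta-Ct method - together with a RefFinder-style consensus ranking by
    geometric mean of per-method ranks. Includes target-gene normalization
    against best and worst reference panels, a synthetic Cq generator with
    known variance structure for method validation, and a bundled bovine
    PBMC benchmark dataset of 10 candidate reference genes across 30
    animals from two contrasting environments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
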