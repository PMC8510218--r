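Package: mixqspr
Title: QSPR Modelling of Binary Mixture Properties with Weighted-Mixture Descriptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative structure-property relationship (QSPR)
    modelling of binary mixtures such as deep eutectic solvents.  Builds
    molar-fraction-weighted mixture descriptors (sum and absolute-difference
    forms) from per-component descriptor tables, enumerates mixtures-out and
    compounds-out train/test divisions controlled by seed and interval
    parameters, and fits multiple linear regression models by sequential
    forward selection with a leave-one-out MAE reduction stopping rule.
    Includes a full validation battery (leave-one-out and leave-chemical-out
    cross-validation, external prediction metrics, rm2 metrics,
    Y-randomization), leverage-based applicability-domain analysis for
    Williams plots, intelligent consensus prediction across model ensembles,
    and a synthetic-data generator with known ground truth for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
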