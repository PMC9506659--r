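Package: vtdisparity
Title: Virtual-Twins Subgroup Discovery for Disparities in Treatment Completion
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-stage virtual-twins analysis of disparities in substance use
    disorder treatment completion on coded categorical discharge cohorts in the
    TEDS-D dialect. Stage one fits flexible completion-probability models
    (random forest, gradient boosted trees, neural network, logistic
    regression) over repeated train/test splits, selects a finalist, and
    predicts each discharge's completion probability under both values of a
    binary disparity attribute (the counterfactual "twin"). Stage two fits a
    best-subset regression tree to the per-record probability differences and
    extracts subgroups with large mean differences. Includes codebook-driven
    cohort I/O and validation, Table-1 style descriptives, a synthetic cohort
    generator with closed-form ground-truth probability differences and
    planted subgroup interactions, SMOTE class balancing for robustness
    checks, and an end-to-end pipeline with an alternate planned-discharge
    outcome coding.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    xgboost,
    nnet,
    yaml,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
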