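Package: cndiag
Title: Compositional Nutrient Diagnosis of Tree Foliar Tissue at Regional and Local Scales
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for factor-specific nutrient diagnosis of foliar tissue
    compositions using Aitchison (log-ratio) geometry. Provides closure with a
    filling value, centered/isometric log-ratio transforms, pairwise log-ratio
    features, Compositional Nutrient Diagnosis (CND-clr) indices against
    reference norms from nutritionally balanced high-yield specimens, quartile
    compatibility intervals with Low/Normal/High classification,
    confusion-quadrant yield partitioning with machine-learning benchmarking
    (AUC, classification accuracy, Monte-Carlo holdout cross-validation,
    feature ablation), and local diagnosis by Euclidean distance to
    factor-matched successful neighbors. Includes a logistic-normal synthetic
    population generator so every stage of the pipeline can be exercised
    without access to proprietary survey data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    MASS,
    ranger
Suggests:
    testthat (>= 3.0.0),
    pROC,
    e1071
Config/testthat/edition: 3
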