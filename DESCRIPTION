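Package: metapairs
Title: Predicting Microbial Cross-Feeding and Competition from Metabolic
    Reaction Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encodes genome-scale metabolic networks as binary
    reaction-presence vectors over a shared reaction pool, represents
    pairs of microorganisms as concatenated vectors with orientation
    augmentation (AB/BA), builds leakage-aware cross-validation folds by
    clustering pairs, and classifies pairwise interactions as
    cross-feeding or competition with an in-package k-nearest-neighbours
    baseline plus adapters for random forest, support vector machine and
    gradient boosting classifiers. Includes precision/recall/F1 and
    ROC/PR evaluation for imbalanced two-class problems, comparison of
    predicted interaction matrices against external potential
    cooperation score (PCPS) matrices via a sign-consensus procedure,
    and a synthetic community generator with planted, tunable
    cross-feeding and competition signal for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    e1071,
    jsonlite,
    randomForest,
    stats,
    tools,
    utils,
    xgboost,
    xml2
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
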