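Package: lncDiseaseBoost
Title: Prediction of lncRNA-Disease Associations from Network Feature
    Similarity and Gradient Boosting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts associations between long non-coding RNAs (lncRNAs)
    and diseases from a known binary association matrix and a MeSH-style
    disease hierarchy. Builds per-disease ancestor DAGs and two semantic
    similarity matrices (a decay-based and an information-content-based
    variant), best-match-average lncRNA functional similarities, and
    Gaussian interaction-profile kernel similarities; fuses them into
    per-pair feature vectors, reduces dimensionality with a single
    hidden-layer sigmoid autoencoder, and classifies pairs with gradient
    boosted regression trees. Ships hold-out, leave-one-out and k-fold
    cross-validation protocols, per-disease candidate ranking, and a
    synthetic planted-cluster benchmark generator so the whole pipeline is
    testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    xgboost,
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
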