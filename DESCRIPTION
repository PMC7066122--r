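Package: fedradiomics
Title: Privacy-Preserving Distributed Modelling of Radiomic Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for training and validating radiomics-based logistic
    regression models on horizontally partitioned multi-centre data without
    sharing patient-level records. Sites exchange only aggregate messages:
    per-feature moment summaries for distributed quality control and
    z-scoring, Fisher z-transformed correlation matrices pooled with inverse
    variance weights for hierarchical feature clustering, weighted
    per-cluster AUC votes for representative selection, and per-iteration
    gradient/Hessian pairs for federated Newton-Raphson (GLORE) logistic
    regression. Centralized reference implementations, model comparison
    statistics (DeLong tests, calibration slope, classification
    discrepancy, Kaplan-Meier with G-rho tests), a leave-one-cohort-out
    comparison workflow and a synthetic multi-site cohort generator are
    included.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    pROC,
    survival,
    e1071
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
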