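Package: alshift
Title: Uncertainty-Based Active Learning for Domain Adaptation in Binary
    Image Screening
Version: 0.1.0
Authors@R:
    person("alshift", "maintainers", email = "maintainers@alshift.dev",
           role = c("aut", "cre"))
Description: Tools for studying pool-based active learning as a domain
    adaptation strategy for binary image classifiers. Provides a seeded
    two-domain synthetic image benchmark with a controllable
    pixel-intensity shift, a compact convolutional classifier trained by
    Adagrad with categorical cross-entropy, least-confidence query
    selection with an iterative label-and-retrain loop, pixel-intensity
    domain-shift diagnostics (normalized histograms and two-sample
    t statistics), a confusion-matrix/AUC evaluation matrix keyed by
    weight snapshot and test set, Grad-CAM explanations, and a
    three-phase experiment orchestrator (source pretraining, active
    learning on the target pool, target-only retraining) with
    reproducible run manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
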