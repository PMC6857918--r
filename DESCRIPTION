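Package: survtopics
Title: Topic-Model Features and Individual Survival Distributions for
    High-Dimensional Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns a high-dimensional gene-expression matrix into a small set
    of "cancer topic" features via a discretized latent Dirichlet allocation
    (dLDA), optionally combines them with clinical covariates and supervised
    principal components, and learns either an individual survival
    distribution (multi-task logistic regression, MTLR) or a proportional
    hazards risk score (Cox, ridge Cox) under right-censoring. Provides
    concordance-index and distributional-calibration (Hosmer-Lemeshow)
    evaluation, a synthetic cohort generator with topic-structured expression
    and topic-driven hazards, and serialization of fitted pipelines for
    prediction on novel patients.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    survival,
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
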