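Package: biopriority
Title: Biopsychosocial Prioritization of Surgical Waiting Lists
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Expert-weighted multi-criteria prioritization of surgical
    waiting lists. Aggregates direct expert ratings into normalized
    criterion weights, transforms mixed-type (ordinal, categorical,
    continuous, binary) biopsychosocial patient data into an
    expert-share normalized decision matrix, computes composite
    priority scores by weighted sum, stratifies patients into priority
    groups by k-means or Gower/k-medoids clustering with diagnostic
    validation (silhouette, PCA projection, permutation MANOVA), and
    compares chronological versus priority-based scheduling with a
    stochastic clinical-impact simulator (Gamma risk progression,
    logistic urgent-hospitalization model, Poisson length of stay,
    Monte-Carlo confidence intervals). Includes a synthetic-cohort
    generator with latent severity groups, a weight-stability
    sensitivity analysis, and a demographic-parity fairness audit.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    cluster,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
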