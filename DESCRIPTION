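Package: hteclust
Title: Clustering Algorithms for Heterogeneity of Treatment Effect in Randomised Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A benchmark framework for discovering patient clusters in
    randomised-controlled-trial data and testing them for heterogeneity of
    treatment effect (HTE). Implements five unsupervised clustering
    algorithms (latent class analysis by EM, k-means, partitioning around
    medoids, hierarchical and spectral clustering), three supervised
    individual-treatment-effect estimators (X-learner, honest causal
    forest, model-based recursive partitioning), consensus-based selection
    of the number of clusters via the proportion of ambiguous clustering
    (PAC), interaction likelihood-ratio HTE testing with per-cluster odds
    ratios, gradient-boosting variable-importance attribution, and
    seed-perturbation stability analysis with the adjusted Rand index.
    Ships a synthetic RCT generator emulating a two-subphenotype critical
    care cohort so the full pipeline is testable without restricted trial
    data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    ranger,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    cluster,
    mclust
Config/testthat/edition: 3
RoxygenNote: 7.3.3
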