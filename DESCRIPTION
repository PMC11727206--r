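Package: modexp
Title: Minimax Optimal Deterministic Experiments for Two-Arm Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Design and evaluation of two-arm treatment assignments in the
    presence of continuous pre-treatment covariates. Quantifies covariate
    imbalance between treatment and control groups by a generalized kernel
    discrepancy (maximum mean discrepancy), and constructs the minimax
    optimal deterministic experiment (MODE): the balanced partition of the
    units minimizing that discrepancy, which minimizes the worst-case mean
    squared error of the difference-in-means estimator over a kernel-bounded
    class of outcome mean functions. Includes energy-distance and centered
    L2-discrepancy kernels, exchange / twinning / CDF-transform / Monte
    Carlo partition optimizers with an exhaustive small-sample oracle,
    randomized baselines (complete randomization, Mahalanobis-distance
    re-randomization, relaxed discrepancy-based re-randomization), maximum
    risk and randomization variance calculators, and a replication engine
    for empirical mean-squared-error and Kolmogorov-Smirnov comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    MASS,
    jsonlite,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
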