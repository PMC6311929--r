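Package: hettree
Title: Recursive Partitioning for Heterogeneous Treatment Effects with
    Multi-Objective Split Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates conditional average treatment effects (CATE) from
    randomized or observational tabular data by recursive partitioning.
    Candidate splits are scored simultaneously on a fitness criterion
    (a maximization surrogate for the unobservable mean squared error of
    the effect estimates) and a heterogeneity criterion (the squared
    difference of child-node effects); the multi-objective criterion keeps
    a bounded epsilon-dominance Pareto archive of candidate score pairs
    and selects the split from it. Baseline criteria (causal-tree fitness,
    maximum heterogeneity, squared t-statistic, transformed-outcome and
    plain regression trees), inverse-propensity-weighted within-node effect
    estimation, four synthetic benchmark designs, and RMSE/weighted-RMSE
    evaluation utilities are included, along with a small command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
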