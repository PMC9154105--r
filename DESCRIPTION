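Package: baselineABC
Title: Simulation-Based Evaluation of Misspecified Population-Genetic Inference
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Forward Wright-Fisher and coalescent simulation of a
    Drosophila-like chromosomal segment under combinations of demography,
    background selection, recurrent selective sweeps, progeny skew, mutation
    and recombination rate heterogeneity, and variant-calling ascertainment
    error, together with an approximate Bayesian computation (ABC) engine
    (rejection sampling, local-linear and neural-network regression
    adjustment, tolerance cross-validation, weighted-median point estimates)
    for fitting deliberately misspecified demographic and recurrent-sweep
    models to the simulated data.  Includes the closed-form fixation
    probability of exponentially distributed beneficial effects and the
    conversion between the beneficial fraction of substitutions (lambda) and
    the beneficial fraction of new mutations (f_pos), a windowed
    summary-statistic panel (site-frequency-spectrum, haplotype and linkage
    disequilibrium statistics), posterior predictive checks, and
    orchestration of figure-level mis-inference experiments at reduced scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    S4Vectors,
    IRanges,
    nnet,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
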