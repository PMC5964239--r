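Package: bisectlab
Title: Temporal Bisection Designs, Two-Stage Diffusion Modelling and EEG
    Time/Frequency Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Computational machinery for sub-second temporal bisection
    experiments: first-order counterbalanced trial sequences built as
    Eulerian circuits of the transition multigraph; a two-stage
    drift-diffusion generative model of bisection choices and reaction
    times, with trial-history (carryover) drift of the categorical
    boundary; cumulative Gumbel psychometric fits with bias-corrected
    bootstrap threshold intervals; carryover and sliding-window
    bisection-point analyses; the Wiener first-passage time likelihood with
    hierarchical Bayesian (MCMC) and maximum-likelihood inversion,
    Gelman-Rubin diagnostics, DIC model comparison and posterior predictive
    checks; Morlet wavelet time/frequency decomposition with per-pixel
    duration regression and cluster-based permutation inference; and
    synthetic behavioral and EEG epoch generators so every stage can be
    exercised without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
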