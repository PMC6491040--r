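Package: metamerscale
Title: Critical-Scale Analysis of Pooled Texture-Statistic Metamers
Version: 0.1.0
Authors@R: person("Metamerscale", "Developers", role = c("aut", "cre"),
    email = "maintainers@example.org")
Description: Tools for testing whether foveated pooling-statistic models of
    peripheral vision produce visual metamers. Implements image
    standardization to fixed luminance statistics, eccentricity-scaled
    radial/angular pooling grids, pooled-feature image synthesis by
    gradient descent with a self-contained oriented filter-bank backend,
    localized Gram-matrix texture distortions, a Monte-Carlo calibrated
    Weibull link between sensitivity and proportion correct in the
    three-alternative oddity task, and hierarchical Bayesian estimation of
    the critical pooling scale from binomial trial data via an adaptive
    Markov chain Monte Carlo sampler. Includes generators for synthetic
    scene-like and texture-like images and for simulated observer data
    with known ground truth, supporting end-to-end parameter-recovery
    studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    data.table,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
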