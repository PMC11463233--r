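Package: collnav
Title: Equilibrium Accuracy and the Evolution of Leadership in Collective Navigation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytic and simulation tools for a linear model of collective
    navigation in which agents repeatedly combine a private, noisy
    environmental signal about a distant target with noisy observations of
    other group members' current estimates. Provides closed-form equilibrium
    target error and inter-agent correlation for homogeneous groups, the
    collectively optimal target weighting and its evolutionarily stable
    counterpart obtained by best-response iteration, the two-type
    (expert/naive) extension with attention weighting between types, a
    mutation-selection simulation in which per-agent information precision is
    costly and leader/follower specialisation can emerge, and Monte Carlo
    simulation of the underlying stochastic update rule used to verify every
    analytic equilibrium.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    Rcpp,
    yaml,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
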