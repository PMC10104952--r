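Package: contextfx
Title: Bayesian Tests for Context Effects in Multiattribute Choice
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Measures and hierarchical Bayesian tests for context effects
    (attraction, similarity, compromise) in two-triplet multiattribute
    choice experiments. Implements the relative choice share of the target
    in its unequal-weights (collapsed-counts) and equal-weights forms, the
    absolute choice shares of target and competitor for regularity tests,
    hierarchical beta-binomial and Dirichlet-multinomial group models with
    exact-conditional Markov chain Monte Carlo, bridge-sampling marginal
    likelihoods and Bayes factors, highest density intervals, Bayesian
    correlations between effects, and a simulation study of the bias that
    unequal sample sizes across choice sets induces in collapsed-count
    inference.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
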