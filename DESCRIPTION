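Package: venomdiv
Title: Family-Level Comparative Analysis of Venom and Diversification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for testing whether a binary key-innovation trait (venom)
    is associated with elevated net diversification at the family level.
    Implements stem-age method-of-moments net diversification estimation with
    relative-extinction sensitivity, phylogenetic generalized least squares
    under selectable trait-evolution covariance models (Brownian motion,
    Ornstein-Uhlenbeck with random or fixed root, Pagel's lambda, kappa,
    delta, early burst, trend, and non-phylogenetic OLS) with maximum
    likelihood fitting and AIC model selection, the richness Yule
    likelihood-ratio sister-clade test, constrained binary-state
    speciation-extinction (BiSSE) and hidden-state (HiSSE-style) likelihoods
    with simulation-based adequacy checks, stochastic character mapping of
    trait origins, and a synthetic-data generator with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phytools,
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    nlme,
    withr,
    phangorn
Config/testthat/edition: 3
RoxygenNote: 7.3.3
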