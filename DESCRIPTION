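Package: glottocoevo
Title: Spatiophylogenetic Tests of Implicational Universals in Language Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for testing implicational universals ("if a language has X,
    then it has Y") between paired binary grammatical traits while controlling
    for genealogical and geographical relatedness. Implements Bayesian binary
    generalized linear mixed models with phylogenetic and spatial covariance
    random effects, dependent and independent continuous-time Markov models of
    paired trait co-evolution with Felsenstein pruning likelihoods, MCMC with
    tree cycling and stepping-stone marginal likelihood estimation for Bayes
    factors, harmonic versus disharmonic transition-rate comparisons, and
    maximum-likelihood marginal ancestral state reconstruction with FitzJohn
    root probabilities and Lewis ascertainment correction. Includes a synthetic
    data generator (pure-birth trees, Brownian geography, family clades,
    simulated traits) so the full pipeline is testable without external
    databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    geosphere,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
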