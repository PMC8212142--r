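Package: isingml
Title: Ising-Formulated Classification with Annealing-Family Solvers
Version: 0.1.0
Authors@R:
    person("isingml", "developers", email = "isingml@example.org",
           role = c("aut", "cre"))
Description: Encodes multinomial classification as an Ising Hamiltonian via a
    second-order expansion of the softmax negative log likelihood, solves the
    resulting quadratic spin problem with simulated annealing, random sampling,
    and field-only heuristics, and turns low-energy spin ensembles into
    classifiers with discrete weights. Includes a classification restricted
    Boltzmann machine trained by one-step contrastive divergence, a
    leakage-free evaluation protocol (stratified resplitting, train-fitted
    z-scoring and PCA, training-fraction sweeps, paired nonparametric tests),
    and seeded generators for block-correlated multi-omics-like synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    glmnet,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
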