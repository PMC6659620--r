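Package: phenoswitch
Title: Stochastic Two-Phenotype Switching Models of Drug-Tolerant Cancer
    Cell Populations
Version: 0.1.0
Authors@R:
    person("phenoswitch", "developers", email = "phenoswitch@example.org",
           role = c("aut", "cre"))
Description: Exact stochastic simulation and closed-form moment analytics for
    a continuous-time Markov branching model of cancer-cell populations that
    switch reversibly between a drug-sensitive (E) and a drug-tolerant (M)
    phenotype. Implements the drug-exposure (no-birth) and growth phases,
    Fano-factor diagnostics for pre-existing phenotypic heterogeneity,
    a designed-initial-condition protocol that estimates switching, birth and
    death rates together with the mean and variance of the initial resistant
    fraction, Beta-distribution characterization of the resistant-fraction
    distribution, a seeded synthetic-experiment generator, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
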