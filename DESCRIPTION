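Package: macroevopaths
Title: Multi-Stage Macroevolutionary Analysis of Diversification, Disparity,
    Biogeography, and Phylogenetic Path Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for studying the joint abiotic and biotic
    drivers of lineage diversification on time-calibrated phylogenies:
    per-tip speciation-rate estimation (the DR statistic) and phylogenetic
    ridge regression for trait-evolution rates; maximum-likelihood fitting
    of constant, time-dependent, and paleoenvironment-dependent birth-death
    models with AICc comparison; morphospace construction (PCA, Gower/PCoA)
    with per-clade disparity, rarefaction, and disparity-through-time
    against a Brownian-motion null (MDI); multi-optimum Ornstein-Uhlenbeck
    regime models with pBIC comparison; time-stratified
    dispersal-extinction-cladogenesis (DEC, optionally +J) ancestral range
    estimation; and phylogenetic path analysis over causal models via
    d-separation, Fisher's C, and CICc model averaging. A synthetic-data
    module simulates trees, traits, ranges, and path datasets with known
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    deSolve,
    Matrix,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster,
    picante,
    nlme,
    optparse
Config/testthat/edition: 3
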