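Package: bfodbn
Title: Bacterial-Foraging Optimization and Two-Slice Dynamic Bayesian Network Structure Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A bacterial-foraging metaheuristic for continuous optimization
    (chaotic logistic-sine population initialization, peer-guided chemotaxis,
    health-ranked crossover reproduction, adaptive elimination-dispersal) and a
    discrete variant of the same search framework that learns the structure of
    two-slice dynamic Bayesian networks (2T-BNs) from multivariate discrete
    sequence data under a dynamic K2 Bayesian-Dirichlet score.  Includes a
    CEC2005-style benchmark-function suite for validating the continuous
    optimizer, a 2T-BN forward sampler for generating synthetic sequence data,
    structural-Hamming-distance evaluation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
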