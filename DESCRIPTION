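Package: pggexclusion
Title: Optional Public Goods Games with Synchronous and Asynchronous Exclusion
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Stochastic evolutionary dynamics of the optional public goods
    game with four strategies (cooperation, defection, non-participation and
    exclusion) under two exclusion mechanisms. Provides exact expected
    payoffs in finite well-mixed populations, construction and solution of
    the ergodic state-space Markov chain (stationary distributions,
    operational stochastic stability, cooperative-state probability
    differences between mechanisms), and an agent-based Monte Carlo
    simulation on a periodic square lattice with Fermi-rule imitation,
    together with parameter-sweep drivers and reproducible output writers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
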