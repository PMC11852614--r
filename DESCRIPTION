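Package: choicesym
Title: Bayesian Choice-Consistency Simulation and Symmetry-Breaking Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Sequential simulator of Bayesian decision-making under choice
    consistency. An agent samples Normal stimuli, selects discrete actions
    from a Gaussian-mixture policy, receives Normal rewards, and re-estimates
    its policy weights every step by derivative-free simplex minimization of
    a lambda-weighted compromise between expected-reward loss and the total
    surprisal of the choices held in a finite memory. Includes batch drivers
    and analysis tools for the emergent phenomena: spontaneous symmetry
    breaking of the stimulus-action map, stoppage times of losing actions, a
    behavior taxonomy (full discrimination, intermingling, sandwich bands,
    switching, non-discrimination), multi-action segmentation statistics, and
    reward-versus-consistency trade-off sweeps.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
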