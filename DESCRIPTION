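Package: neurocal
Title: Neural Parameter Calibration for Differential-Equation Models of Interacting Agents
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calibrates parameters of ordinary and stochastic differential
    equation models of interacting agents by training a small neural network
    through a differentiable numerical solver, and turns the loss values
    visited during training into posterior marginal densities for the
    parameters. Ships two fully worked systems: a diffusive SIR epidemic
    (agent-based ground truth plus an SDE surrogate) and the Harris-Wilson
    model of demand flow on a bipartite origin-destination network, each with
    a synthetic-data generator so the whole pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    rlang,
    ggplot2,
    generics,
    readr,
    yaml,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr, optparse
Config/testthat/edition: 3
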