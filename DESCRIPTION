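Package: capsonet
Title: Chaos-Enhanced Accelerated Particle Swarm Training of Deep QSPR
    Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Trains deep feedforward regression networks for quantitative
    structure-property relationship (QSPR) modelling with a chaos-enhanced
    accelerated particle swarm optimizer (CAPSO): the social coefficient
    evolves on the logistic map at full chaos and the cognitive coefficient
    decays geometrically, so the swarm anneals from global exploration to
    local refinement without velocity or personal-best bookkeeping.
    Includes the flat particle encoding of network weights and biases, an
    energy-binned stratified data splitter, AARD/RMSEP/R-squared evaluation
    reports, a hidden-node architecture search, and a synthetic molecular
    descriptor generator for absorption-energy data so the whole pipeline
    runs without external datasets.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
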