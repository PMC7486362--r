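Package: itinerant
Title: Attractor Itinerancy in Networks of Bistable Neural Populations
    with Short-Term Synaptic Depression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates networks of recurrently coupled neural populations
    whose mean firing rates are bistable due to strong self-excitation and
    whose synapses undergo short-term depression on a slow timescale.
    Provides the dimensionless three-variable rate model (rate, synaptic
    activation, depression), enumeration and linear-stability classification
    of all fixed points by multi-start root solving, basin-of-attraction
    mapping for two-population circuits, stimulus-response and
    history-dependence diagrams under square-pulse inputs, and statistics of
    attractor-state transition sequences (itinerancy) under repeated
    stimulus trains, including random-network ensembles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
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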