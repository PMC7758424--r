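Package: accumem
Title: Memory-Guided Evidence Accumulation for Decision Making
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A seeded, configurable simulator of memory-based decision
    making. Multi-attribute perceptual scanning feeds a recurrent memory
    network with fast semantic attractors, synaptic-depression latching and
    delayed episodic sequence recall; valued memory states drive
    spatially-indexed leaky competing accumulators under stochastic
    attention with top-down feedback, producing choices and reaction times.
    Includes scenario generators, parameter sweeps, and an implicit
    temporal-discounting break-point analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
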