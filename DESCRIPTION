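Package: spineml
Title: Read, Validate and Simulate Declarative Spiking Neural Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A reference implementation of the SpineML three-layer XML dialect
    for networks of spiking point neurons. Reads, validates and writes
    component definitions (hybrid dynamical systems with regimes, triggers and
    event/impulse/analogue ports), network descriptions (populations,
    projections, synapses, and the low-level group/input extension for
    non-synaptic communication such as gap junctions) and experiment
    descriptions (integration settings, inputs, log requests). Networks are
    elaborated into a flat instance graph and simulated with a deterministic
    fixed-step interpreter (forward Euler or classical Runge-Kutta), with CSV
    logging and inter-spike-interval statistics. Includes programmatic builders
    for standard model fixtures, including the Vogels-Abbott excitatory and
    inhibitory benchmark network.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
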