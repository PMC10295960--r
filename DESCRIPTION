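Package: snsim
Title: Design, Compilation and Simulation of Synthetic Nervous Systems
Version: 0.1.0
Authors@R:
    person("snsim", "developers", email = "snsim@example.org", role = c("aut", "cre"))
Description: Tools for designing and simulating synthetic nervous systems:
    heterogeneous networks of conductance-based non-spiking, spiking
    (adaptive-threshold integrate-and-fire) and ion-channel-bearing neurons
    connected by graded chemical synapses, spiking chemical synapses with
    propagation delays, and (optionally rectified) electrical synapses.
    Networks are authored programmatically from reusable neuron, channel and
    connection presets, compiled into flat parameter vectors and matrices,
    and advanced in discrete time with a forward-Euler scheme using either a
    dense vectorised backend or a synapse-iterating backend.  Includes JSON
    network serialisation, CSV stimulus/trace handling, a command-line
    driver, benchmark network generators, and worked examples: a
    Braitenberg-style LiDAR steering controller, a motoneuron-to-muscle
    activation mapping and a persistent-sodium half-centre oscillator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
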