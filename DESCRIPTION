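Package: dorsalhorn
Title: Mechanisms of Excitatory-Inhibitory Dysregulation in Dorsal Horn
    Pain-Processing Subcircuits
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Firing-rate population models of feedforward dorsal-horn
    subcircuit motifs implicated in static and dynamic allodynia, together
    with the analysis pipeline built on them: analytic characterisation and
    uniform sampling of the allowable parameter space (APS) of synaptic
    coupling strengths consistent with healthy gate-control behaviour,
    construction of the allodynia surface in coupling-strength space,
    shortest-path projection of APS points onto that surface via a relaxed
    constrained optimisation, and density-based clustering of the
    shortest-path directions into candidate allodynia mechanisms (release
    from, or escape of, inhibitory control).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
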