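Package: cabletree
Title: Compartmental Neuron Modelling with an Implicit Branched-Cable Solver
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A self-contained compartmental neuron simulator organised as a
    federation of small components: a model container that stores biological
    neuron models (cells, dendritic segments, ion channels, synapses) as a
    slash-addressed tree and translates specific membrane parameters into the
    actual per-compartment values a solver needs; a Hodgkin-Huxley channel
    library with linoid, exponential and sigmoid rate functions; an implicit
    Crank-Nicolson cable solver using Hines tree elimination; a fixed-step
    scheduler with text output sinks and event-driven dual-exponential
    synapses; a declarative model file dialect (NDF) with a shipped channel
    library; a loader for a restricted legacy SLI command subset; an
    interactive shell; and an importer that reduces serial-section EM contour
    stacks to equivalent cylinders for cable modelling.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
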