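Package: coecn
Title: Simulation of Conductance-Based Organic Electrochemical Neurons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Desk-scale circuit simulator for conductance-based organic
    electrochemical neurons (c-OECNs) built from antiambipolar organic
    electrochemical transistors (OECTs). Provides steady-state device laws
    for the Gaussian-shaped (antiambipolar) sodium-branch OECT and the
    standard potassium-branch OECT, electrolyte-dependent modulation of
    device parameters by ions and neurotransmitters, stiff ODE integration
    of the two-node spiking circuit, stimulus-program construction with
    seeded Ornstein-Uhlenbeck noise, spike detection and a battery of
    neurocomputational feature classifiers (excitability classes, stochastic
    spike skipping, energy metrics), a canonical Hodgkin-Huxley reference
    model, and experiment drivers for excitability-class scans and
    event-based chemical sensing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    deSolve,
    jsonlite,
    stats,
    utils,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse
Config/testthat/edition: 3
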