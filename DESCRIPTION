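Package: fragilenet
Title: Closed-Loop Control of Fragile Neuronal Networks
Version: 0.1.0
Authors@R:
    person("Daniel", "Reyes", email = "dreyes@example.org", role = c("aut", "cre"))
Description: Simulation and closed-loop control of a fragile (epileptic)
    neuronal network. Provides an event-driven Gillespie simulator for a
    stochastic binary-neuron network with a saturating response function,
    fixed-point and linear-stability (functional connectivity) analysis,
    minimum-energy single-row destabilizing perturbations (nodal fragility),
    a two-mode hidden-Markov-model instability detector operating on
    windowed firing rates via a cumulative likelihood-ratio statistic, and
    linear- and nonlinear-model state-feedback controllers that return a
    destabilized network to its stable mode. Includes a synthetic network
    generator, a benchmark harness for detection and control performance
    metrics, plain-text (CSV/JSON) readers and writers, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
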