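Package: mbplast
Title: Dual-Transmitter Synaptic Plasticity Model of Drosophila
    Mushroom-Body Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and fits a two-pathway (dopamine and nitric oxide)
    model of synaptic plasticity at Kenyon-cell-to-output-neuron synapses
    in the Drosophila mushroom body. Provides exact propagation of fast
    eligibility and slow expression variables under piecewise-constant
    optogenetic stimulation schedules, a softmax behavioural readout
    yielding the olfactory-arena performance index, builders for
    acquisition, retention, reversal, neuron-only and odor-only training
    protocols, staged grid-search inference of the plasticity rate
    constants from behavioural data, and a synthetic arena-assay
    generator with binomial choice noise and reciprocal odor design for
    parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
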