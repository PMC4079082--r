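Package: striatlearn
Title: Spiking-Network Model of Procedural Category Learning and Feedback Timing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates a spiking basal-ganglia network (cortex -> striatal
    medium spiny neurons -> globus pallidus -> thalamus -> premotor units)
    that learns information-integration categories through dopamine-gated
    three-factor plasticity at cortical-striatal synapses. Synaptic change on
    each trial is driven by the temporal overlap of a lagged, smeared
    glutamate trace and a dopamine trace (both alpha functions), which makes
    learning sensitive to the delay between response and feedback: best near
    500 ms, degraded at 0 and 1000 ms, and absent at 2.5 s or longer.
    Includes generators for rule-based and information-integration category
    structures, a Bush-Mosteller reward-prediction module driving phasic
    dopamine, experiment orchestration with replication-level learning
    curves, and a strategy-mixture accuracy model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    tools,
    Rcpp,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
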