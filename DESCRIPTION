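Package: acxsim
Title: Rate and Spiking Models of the Auditory Cortical PV-SST-Exc Microcircuit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates an auditory-cortex microcircuit of excitatory, parvalbumin-
    positive (PV) and somatostatin-positive (SST) neural populations at two levels
    of description: a dimensionless Wilson-Cowan rate model (single iso-frequency
    unit and a three-unit tonotopy with depressing and facilitating synapses and a
    paradigm-dependent baseline-inhibition regime), and a conductance-based
    adaptive exponential integrate-and-fire spiking network with two-compartment
    pyramidal neurons. Ships generators for four auditory/optogenetic paradigms
    (oddball stimulus-specific adaptation, forward suppression, tuning-curve
    adaptation, PV activation), summary metrics (common-contrast SSA index,
    onset-aligned thalamo-cortical correlation, excitatory-inhibitory current
    balance), and experiment drivers that reproduce the circuit-level effects of
    optogenetic PV and SST perturbations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
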