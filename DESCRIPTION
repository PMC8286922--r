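Package: bgloop
Title: Spiking Network Model of the Basal Ganglia-Thalamo-Cortical Loop
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulator for the basal ganglia-thalamo-cortical circuit built
    from extended Izhikevich point neurons (cortical regular- and
    fast-spiking cells, D1- and D2-type striatal medium spiny neurons,
    pallidal pacemakers, subthalamic and thalamocortical relay neurons).
    Dopamine enters as a tonic plus stimulus-locked phasic level that
    modulates striatal excitability and cortico-striatal synaptic gain,
    switching the circuit between direct- and indirect-pathway dominance.
    Includes random-graph network construction with conduction delays,
    pair-based spike-timing-dependent plasticity with structural rewiring,
    Poisson background drive, five healthy/Parkinsonian simulation
    scenarios, and an analysis pipeline for population firing rates,
    spectrograms, frequency-band classification, pairwise synchrony and
    partial directed coherence.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
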