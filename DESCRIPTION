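Package: pfcwm
Title: Spiking Network Model of Prefrontal Working Memory Under Dopamine
    and Norepinephrine Modulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a columnar spiking network model of dorsolateral
    prefrontal cortex performing the oculomotor delayed-response task.
    Izhikevich point neurons with conductance-based AMPA, NMDA, GABA-A and
    GABA-B synapses are organised into four direction-tuned two-layer
    cortical columns plus parietal input, thalamic corollary-discharge,
    basal-ganglia clearing and motor-output areas. Dopamine (D1) and
    norepinephrine (alpha-2A, alpha-1) levels act as multiplicative gain
    factors on recurrent excitation, lateral excitation and total synaptic
    current, reproducing the inverted-U dose-response of delay-period
    persistent activity and a 3x3 grid of behavioral outcomes across
    low/optimal/high neuromodulator levels. Includes trial-protocol
    generation, an accumulator saccade readout, firing-rate analysis and a
    weight-calibration routine, with a compiled core for fast simulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
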