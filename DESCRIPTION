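Package: bgnet
Title: Spiking Basal Ganglia Network Model of Transient Responses and
    Beta-Band Pathology
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a reduced spiking network model of the basal ganglia
    (striatal D1/D2 spiny projection neurons, fast-spiking interneurons,
    subthalamic nucleus, arkypallidal and prototypical globus pallidus
    externa, and substantia nigra pars reticulata) with leaky
    integrate-and-fire and adaptive exponential integrate-and-fire neurons
    coupled by conductance-based alpha synapses. Provides dopamine-dependent
    parameter presets for healthy and low-dopamine (parkinsonian) conditions,
    calibrated Poisson background drive, rate-modulated transient cortical
    stimulation, peristimulus-time-histogram zone segmentation of the nigral
    transient response (early/late excitation and inhibition), beta-band
    oscillation index, population Fano factor, Hilbert-phase relationships,
    and scripted perturbation experiments (weight sweeps, restorations,
    lesions, dopamine sweeps, phase-conditioned stimulation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
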