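Package: eicortex
Title: Excitatory-Inhibitory Homeostasis and Metastable Dynamics in
    Large-Scale Cortical Network Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Simulates large-scale models of the human cortex in which every
    region is a Wilson-Cowan excitatory-inhibitory neural mass with conduction
    delays, or a reduced Wong-Wang mass with slow NMDA-timescale excitation,
    and the parameters of each region are solved analytically so that multiple
    mechanisms of excitatory-inhibitory homeostasis (synaptic scaling of
    excitation and inhibition, plasticity of intrinsic excitability) hold the
    mean excitatory rate at a target set point. Includes a Balloon-Windkessel
    hemodynamic forward model, the observable suite used to benchmark such
    models against resting-state fMRI (band-passed functional connectivity,
    functional connectivity dynamics with Kolmogorov-Smirnov distances, a
    cross-feature fitting score, Kuramoto synchrony and metastability,
    functional complexity), synthetic modular connectome generation, and the
    computational experiments built on top: validity-gated parameter sweeps,
    noise sweeps, shuffled-connectome controls, and the healthy/acute/chronic
    focal-lesion protocol with homeostatic recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    signal,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    deSolve
Config/testthat/edition: 3
RoxygenNote: 7.3.3
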