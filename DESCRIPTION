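Package: spinesim
Title: Stochastic Simulation of Hippocampal Synaptic Plasticity Induction
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Event-based stochastic simulation of plasticity induction at a single
    CA3-CA1 dendritic spine. Couples a two-pool stochastic vesicle-release model,
    a three-compartment electrical model with back-propagating action potentials,
    stochastic Markov-chain receptors and channels (AMPAr, GluN2A/GluN2B NMDAr,
    GABA(A)r, T/R/L-type VGCC), Goldman-Hodgkin-Katz calcium influx with a generic
    buffer and optional dye, and a deterministic coarse-grained CaM-CaMKII-CaN
    enzyme network. Joint CaN-CaMKII activity is classified by a geometric readout
    (polygonal LTP/LTD regions driving a stochastic plasticity chain) into
    potentiation, depression or no change, under configurable experimental
    conditions (age, temperature, extracellular Ca/Mg, distance from soma) and
    stimulation protocols (STDP pairings, frequency trains, theta-burst, jittered,
    sparse and Poisson trains).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Matrix,
    stats,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    generics,
    ggplot2
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
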