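Package: picovir
Title: Infection Kinetics, Titration and Cell-Cycle Analysis for Lytic
    Algal Virus Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantitative analysis of batch-culture infection experiments
    with lytic viruses of picophytoplankton. Provides maximum-likelihood
    Most Probable Number (MPN) estimation of infectious titre from
    serial-dilution well outcomes with confidence intervals, infectivity and
    multiplicity-of-infection calculations, DNA-content (SYBR) cell-cycle
    gating of flow-cytometry event tables with an infected-fraction
    correction for dividing cells, population-dynamics estimators (log2
    fold change, specific growth rate, latent period, burst size, viral
    production and light-sensitivity ratios) with the accompanying
    statistical-testing protocol, a dsDNA genome-replication energetic cost
    model, and a stochastic discrete-time simulator of the full experiment
    (diel-synchronized host growth, adsorption, latency, burst and
    reinfection) that generates every pipeline input with known ground
    truth for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Collate:
    'picovir-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'simulate.R'
    'mpn.R'
    'cellcycle.R'
    'kinetics.R'
    'energetics.R'
    'io.R'
    'pipeline.R'
RoxygenNote: 7.3.3
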