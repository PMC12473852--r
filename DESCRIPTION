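Package: plantmc
Title: Molecular-Communication Modeling of Inter-Plant Stress Signaling
    via Volatile Organic Compounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates chemical signaling between plants treated as a
    molecular-communication link. A stressed transmitter plant emits a
    stress-specific biogenic volatile organic compound (BVOC) whose
    synthesis is driven by a gene-regulation ODE feeding aqueous, lipid
    and gas-phase storage pools; the compound propagates through air by
    drift and diffusion to a receiving plant modeled as a perfectly
    absorbing sphere; leaf uptake converts the arrived mass into absorbed
    tissue mass; and a multi-molecule threshold demodulator identifies
    the stress type. Provides closed-form first-hitting-time densities,
    peak times and hit probabilities, a Gaussian signal/interference/noise
    symbol model with a closed-form detection error rate, Brownian-particle
    and symbol-trial Monte Carlo validators, and a configuration-driven
    parameter-sweep runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    yaml
Suggests:
    deSolve,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
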