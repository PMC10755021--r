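Package: sabrefit
Title: SABRE Receptor Model: Dose-Response Fitting with an Explicit Signal Amplification Gain
Version: 0.1.0
Authors@R: person("sabrefit", "developers", role = c("aut", "cre"), email = "sabrefit@example.org")
Description: Implements the SABRE quantitative receptor model, which describes
    pharmacological response as a function of ligand concentration with explicit
    parameters for binding affinity (Kd), receptor-activation efficacy (epsilon),
    constitutive activity (epsilon_R0), pathway signal amplification or
    attenuation (gain gamma, with gamma < 1 producing responses right-shifted
    versus occupancy), and Hill slope. Provides a constrained global
    nonlinear least-squares engine with parameter sharing across ligands and
    pathways, occupancy/response transforms, kappa (Kd/EC50) shift analysis,
    biased-agonism diagnostics, a synthetic concentration-response panel
    generator, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
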