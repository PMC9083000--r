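Package: ezmt
Title: Electrostatic Exclusion-Zone Modelling Around Tubulin Assemblies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form linearized Poisson-Boltzmann electrostatics for
    charged cylinders, spheres and planes in a screening electrolyte, coupled
    to deterministic overdamped Langevin dynamics of a repelled tubulin-dimer
    probe. Computes exclusion-zone (EZ) growth curves, electrostatic energy
    variation profiles and exponential force-law fits for
    microtubule-tubulin, tubulin-tubulin and tubulin sheet-tubulin
    interactions at arbitrary monovalent salt concentrations, together with a
    scenario pipeline, a YAML configuration layer and a randomized scenario
    generator for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    deSolve,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
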