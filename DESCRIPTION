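Package: poreflux
Title: Water Permeation, Pressure-Driven Flux and Bilayer Structure Analysis
    for Channel-in-Membrane Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for molecular-simulation studies of water
    transport through a membrane-embedded channel, such as an aquaporin
    stabilized in a solid-state nanopore. Implements the region-based
    constant-force scheme that generates a hydrostatic pressure difference
    across a membrane under periodic boundary conditions, directed counting
    of water permeation events through a cylindrical channel with a sealing
    check for the surrounding lipid annulus, inference of hydraulic
    permeability from flux-pressure data and its conversion to osmotic
    permeability, and structural-stability profiling of the lipid bilayer
    (radial thickness, axial density, hydrocarbon-chain elongation, backbone
    RMSD). A seeded synthetic-trajectory generator with analytic ground
    truth makes the whole pipeline testable without a molecular-dynamics
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
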