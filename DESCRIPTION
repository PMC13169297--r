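Package: puckerpath
Title: Ring Puckering, Enhanced-Sampling Surrogates and Free-Energy Path
    Analysis for Polysaccharide-Lyase Mechanisms
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Desk-scale analysis toolkit for the conformational and reaction
    free-energy landscapes of six-membered sugar rings in polysaccharide-lyase
    active sites. Computes Cremer-Pople puckering coordinates and classifies
    ring conformers against the canonical pyranose conformer sphere, evaluates
    distance-combination reaction collective variables for syn beta-elimination,
    runs Langevin dynamics and well-tempered metadynamics on analytic model
    potentials, performs umbrella sampling with a WHAM solver, post-processes
    gridded free-energy surfaces (minima, minimax minimum free-energy paths,
    barriers, tube averages), assigns conformational itineraries, and tests
    product-ring conformations against the unsaturated-product pathway relation
    theta = 90 + 39*cos(phi - 270). Ships seed-deterministic synthetic-data
    generators (ideal ring geometries, pucker trajectories, surrogate
    landscapes) plus readers and writers for PLUMED-style COLVAR/HILLS/grid
    text files.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    bio3d,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
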