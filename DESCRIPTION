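Package: salrshell
Title: Self-Assembly of SALR Colloids Confined in Narrow Spherical Shells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Grand-canonical Monte Carlo simulation of colloidal fluids with
    competing short-range attraction and long-range repulsion (square-well-linear
    SALR potential) confined between concentric hard spherical walls, together
    with the analysis used to identify the self-assembled cluster structures:
    three-dimensional local-density accumulation with iso-density surface
    extraction, bond-graph cluster identification and tube/loop topology
    classification, and a geometric model that predicts the admissible
    structures by optimal packing of tori and spheres in a shell of fixed width
    and enumerates the derived (hemisphere-rotation) and hybrid structures.
    Includes ideal decorated configurations of the model structures so every
    analysis stage is testable without long simulations, and a small
    command-line surface for simulation, analysis, prediction and fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
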