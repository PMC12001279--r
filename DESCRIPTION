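Package: morphofold
Title: Mechanical Morphogenesis of Skin Folding by Differential Growth
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates growth-driven folding of layered embryonic skin with a
    morphoelastic neo-Hookean finite-element model (multiplicative
    decomposition of the deformation gradient into elastic and growth parts,
    damped explicit relaxation to steady state with penalty contact), extracts
    fold networks from deformed surfaces via minimum principal curvature and
    raster skeletonization, summarises them with a two-component
    cycle/incomplete-edge metric, calibrates layer material and growth
    parameters against target networks with seeded Bayesian optimization, and
    detects nuclei in 3D volumes by Hessian-curvature blob scoring with
    layer-clipped box density estimation. Includes seeded generators for
    layered tetrahedral meshes, labelled nuclei volumes and labyrinthine
    target networks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    jsonlite,
    igraph,
    yaml,
    lhs
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    tiff,
    ggplot2,
    withr
Config/testthat/edition: 3
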