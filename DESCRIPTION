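Package: molartopo
Title: Dental Topographic Analysis of Chewing-Surface Meshes
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the form of molar occlusal surfaces from triangle
    meshes using dental topographic analysis: Dirichlet normal energy (DNE,
    with convex/concave partition and top-percentile trimming), relief index
    (RFI), orientation patch count rotated (OPCR), ambient-occlusion
    wear-resistance (PCV), three-dimensional surface area and two-dimensional
    projected occlusal area. Includes PLY/STL/OFF mesh input and output, a
    preprocessing chain (cleaning, quadric edge-collapse decimation, Taubin
    smoothing, rigid rotation), a parametric generator of cusped and crested
    molar-like test surfaces with a wear operator, an orientation-sensitivity
    protocol summarised by coefficients of variation, and a statistical layer
    with exact rank tests, effect sizes, Pearson correlation matrices and
    fixed-effect model enumeration ranked by AICc.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    lme4,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
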