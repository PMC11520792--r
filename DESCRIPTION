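Package: toothrep
Title: Accuracy Assessment of CBCT-Derived Tooth Replicas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how faithfully a cone-beam computed tomography
    (CBCT) scan and a milled physical replica reproduce the surface of a
    natural tooth. The package segments CBCT-like volumes into triangulated
    surface models (Hounsfield thresholding, root-canal filling, isosurface
    extraction), performs surface-based rigid registration (iterative closest
    point with exact point-to-triangle correspondences), and computes
    per-vertex Euclidean and signed normal deviation fields with summary
    statistics and blue-to-yellow colour-mapped meshes. A parametric
    tooth-phantom generator (superellipsoid crown, tapered roots, pulp canals,
    CBCT-like voxelisation with partial-volume blur and noise, simulated
    milling error) provides ground-truth inputs so the whole pipeline is
    testable end to end without any scanner data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
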