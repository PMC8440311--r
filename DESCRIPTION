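Package: trabesim
Title: Finite-Element Localization of Trabecular Bone Damage from DXA and
    Micro-CT Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-based linear-elastic finite-element toolkit for localizing
    incipient damage in trabecular bone cores. Provides micro-CT style image
    preprocessing (Gaussian filtering, Otsu segmentation, component cleanup)
    and BV/TV morphometry, direct voxel-to-hexahedron and pixel-to-quadrilateral
    meshing with mesh-quality reporting, an in-package sparse solver for
    plane-strain quadrilaterals and trilinear hexahedra, the strain index of
    bone (SIB) with per-section profiles, two-level sub-modeling down to the
    single-trabecula scale, Woehler (S-N) power-law fatigue regression with
    t-based prediction bounds, and seeded generators for trabecular phantoms,
    DXA-like projections and fatigue datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    tiff
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
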