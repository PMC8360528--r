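Package: retinosmooth
Title: Topology-Preserving Smoothing of Retinotopic Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Quasiconformal smoothing of noisy retinotopic maps on
    triangulated cortical patches. Given a disk-topology surface patch
    flattened to the unit disk and per-vertex visual-field coordinates
    estimated by population receptive field (pRF) modelling, the smoother
    alternates Beltrami-coefficient projection ("chopping"), a Linear
    Beltrami Solver, and weighted Laplacian smoothing until the mapping to
    visual-field coordinates has Beltrami magnitude below one everywhere,
    i.e. zero flipped triangles. Includes harmonic disk flattening,
    geodesic patch extraction, extended polar-angle coding across
    V1/V2/V3, baseline smoothers, a pRF forward model and decoder, and
    synthetic benchmark generators with distortion metrics and
    permutation tests.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
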