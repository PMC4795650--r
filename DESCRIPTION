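Package: adaptivetrack
Title: Contour Tracking on Adaptive Quadtree and Octree Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Contour-based object tracking for 2D and 3D image sequences in
    which every field (level set, optical flow, sparse corruption, relaxed
    segmentation indicator) lives on an adaptive quadtree or octree grid that
    is finest at the moving front. Implements Whitney refinement around a
    signed-distance function, ghost-node finite differences at T-junctions,
    semi-Lagrangian level-set advection and reinitialization, robust optical
    flow with joint sparse-error estimation, and convex-relaxed weighted
    total-variation segmentation with dynamic shape priors, together with a
    synthetic-sequence generator and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    png,
    tiff,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
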