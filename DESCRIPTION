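Package: astrotile
Title: Astrocyte Branch Morphometry, Territory Tiling and Growth Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify astrocyte branching morphology and territorial
    tiling from 2-D microscopy-like images: binarization, homotopic
    skeletonization, skeleton-graph extraction with branch lengths in the
    orthogonal-1/diagonal-sqrt(2) convention, soma-seeded cell assignment,
    topological branch orders, bounding-rectangle coverage, and detection of
    tiling violations (branches of one cell touching or overriding branches of
    another). Includes an agent-based synthetic culture generator in which
    branch tips grow by candidate rejection away from occupied space (contact
    repulsion), an excitotoxic-retraction perturbation, SWC and TIFF
    interchange, and the accompanying statistics: mean plus or minus s.e.m.
    time courses, reference-normalized series, per-image Pearson correlation
    matrices of marker intensities, and one-way ANOVA with Tukey or
    Tukey-Kramer post-hoc comparisons.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    tiff,
    stats,
    utils,
    grDevices,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
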