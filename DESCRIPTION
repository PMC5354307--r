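Package: myovol
Title: Three-Dimensional Reconstruction of Smooth-Muscle Direction Fields
    from Serial Histological Sections
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Semi-automated reconstruction of a weighted three-dimensional
    smooth-muscle direction field (~50 micrometre voxels) from serial
    H&E-stained histological sections. Extracts nuclear ellipses by local
    colour thresholding, coarse-grains nuclear orientation into regional
    direction maps, registers slides rigidly and elastically with a
    generalised Hough transform, assembles uniformly spaced representative
    slides, infers full 3D headless fibre directions by boundary-distance
    maximisation, weights voxels by stereologically corrected nuclear
    density and orientation homogeneity, segments fascicles with a
    double-angle watershed-with-merging, masks vasculature and placental
    tissue, and measures bundle widths with equivalence statistics.
    Includes a synthetic-phantom generator so the whole pipeline is
    testable without real slide scans.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    RNifti,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
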