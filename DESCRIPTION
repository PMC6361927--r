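Package: vimloc
Title: Geometry, Phantoms and Multi-Atlas Segmentation for Localizing the
    Ventro-Intermediate Thalamic Nucleus
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the spatial localization of the
    ventro-intermediate thalamic nucleus (Vim), the surgical target for
    drug-resistant tremor, relative to indirect stereotactic targeting and
    automated segmentation. Implements the quadrilatere-of-Guiot landmark
    construction with a reproducibility harness, the eight-subregion
    bounding-cuboid subdivision of a region of interest, containment,
    adjacency and centroid spatial relations, volume and Dice overlap
    metrics, decile-based (Nyul-style) intensity standardization, weighted
    multi-atlas label fusion with a leave-one-out evaluation harness, and a
    synthetic thalamic-anatomy phantom generator that provides ground truth
    for every stage without patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    RNifti,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
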