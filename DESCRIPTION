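Package: protrudyn
Title: Protrusion-Resolved Boundary and Cortical Dynamics of Migrating Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies amoeboid cell migration from segmented fluorescence
    time-lapse movies at the resolution of individual membrane protrusions.
    The pipeline segments and tracks cells, extracts a 100-point subpixel
    boundary per frame, measures per-point boundary motion, signed local area
    change and Pratt-fit curvature, quantifies normalized cortical myosin II
    intensity in 100 cortical sections partitioned into front, rear and side
    regions, detects and classifies high-curvature protrusions, computes
    offset correlations with bootstrap confidence intervals and
    threshold-persistence curves, and stratifies protrusions into high- and
    low-directionality states through a PCA-based composite directionality
    index with first-order transition statistics. A synthetic amoeboid-cell
    movie generator with scripted protrusion schedules and known cortical
    intensity pools makes every stage verifiable without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    mgcv,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
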