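Package: osteobox
Title: Long-Bone Segmentation and Oriented-Box Morphometry for Micro-CT
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Semi-automated measurement of long-bone lengths from whole-body
    micro-CT volumes. Reads DICOM series or TIFF raster stacks with physical
    voxel spacing and Hounsfield calibration, segments mineralised bone by
    preset or maximum-entropy global thresholding followed by 2D morphological
    clean-up (fill holes, outlier removal, erosion, distance-transform
    watershed), labels 3D connected components, resolves user-supplied seed
    landmarks to named bones, and measures each bone via the minimum bounding
    box aligned with the principal axes of its inertia tensor, with the
    maximum Feret diameter as a comparator. Includes batch reporting
    (left/right and intra-limb ratios, cross-batch coefficient of variation)
    and a ground-truthed synthetic capsule phantom generator for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    igraph,
    tiff,
    yaml,
    grDevices,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
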