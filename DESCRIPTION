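Package: tubemorph
Title: Automated Morphometry of Endothelial Tube Formation Assay Images
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Label-free quantification of endothelial tube formation assay
    (TFA) images. Bright-field TIFF micrographs are converted to grayscale,
    tube-like structures are segmented by Canny edge detection followed by
    morphological bridging, hole filling and speck cleaning, and the resulting
    mask is reduced to a one-pixel backbone by topology-preserving thinning.
    From the mask and backbone the package reports total tube length, tube
    area, average thickness and consolidated branch-point counts, in single
    image or batch mode with reusable parameter profiles and overlay TIFF
    output. A synthetic phantom generator renders line networks with
    analytically known length, area and junction counts for validation,
    including rotated, branched, grid and salt-and-pepper-noise variants.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    EBImage,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
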