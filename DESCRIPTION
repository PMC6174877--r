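Package: colorCard
Title: Color-Card Based Image Standardization for Plant Phenotyping
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Standardizes the brightness, contrast and color profile of
    image sets that contain a 24-chip reference color card, for use in
    high-throughput plant phenotyping. A per-channel cubic polynomial
    color transform is fitted by least squares from homologous card
    chips in a source and a reference image and applied to every pixel;
    the deviance of each image from the reference is scored as one minus
    the determinant of the 9x9 color homography. Includes fixed-threshold
    plant segmentation with a panel of 19 shape descriptors, hue
    histograms of masked pixels with two-sample Kolmogorov-Smirnov
    comparisons, a seeded synthetic-scene generator with full ground
    truth for validating corrections, and a batch pipeline with a
    command-line interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    png,
    tiff,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'color-model.R'
    'io.R'
    'chip-sampling.R'
    'segmentation.R'
    'shapes.R'
    'hue.R'
    'synthetic.R'
    'pipeline.R'
    'colorCard-package.R'
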