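Package: microspot
Title: Spot Detection, Geometric Correction and Quantification for
    Fluorescence Protein Microarray Images
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of small fluorescence protein-microarray images taken
    under non-ideal optics, such as a smartphone camera with a UV-excitation
    attachment. Bright positive-control spots are detected as connected
    components, matched to a known array layout, and used to estimate a
    two-stage geometric correction (an affine transformation followed by a
    quadratic polynomial transformation) that maps the aberrated image onto a
    standardized grid. Each spot is then quantified as the median luminance
    inside an elliptical region of interest, replicate spots are averaged,
    the negative-control background is subtracted and values are normalized
    against the positive control on the same chip. A synthetic scene
    generator with known ground truth supports end-to-end validation, and a
    command-line interface covers analysis, simulation and replicate
    combination.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    png,
    tiff,
    jpeg,
    yaml,
    jsonlite,
    igraph,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
biocViews: CellBasedAssays, Proteomics, Visualization, QualityControl
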