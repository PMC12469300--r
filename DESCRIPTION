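Package: mechmorph
Title: Image-Derived Morphometry of Mechanically and Chemically Stimulated Cells
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for single-cell microscopy endpoints used in
    mechanobiology studies of osteosarcoma cell lines: moment-equivalent ellipse
    morphometry of nuclei with the stretch-reorientation statistic cos(2*phi) and
    nuclear-to-cytoplasmic area ratio, box-counting fractal dimension of
    one-pixel cell-edge masks extracted from AFM height maps or fluorescence
    images, peripheral RMS roughness, corrected total cell fluorescence (CTCF)
    of nuclear Src with ring-based background estimation, and the study-level
    statistics layer (pooled-variance t tests, orientation class fractions,
    detachment and wound-closure percentages). A synthetic-image generator with
    per-object ground truth emulates the measurement contexts (nucleus fields,
    fractal cell contours, pseudo-AFM height maps, two-channel fluorescence
    cells) so every estimator is validated closed-loop against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    yaml,
    tiff,
    png,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
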