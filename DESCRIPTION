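Package: halocount
Title: Single-Molecule Counting of Low-Abundance Proteins in Bacterial
    Epifluorescence Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Counts very low-abundance proteins in fixed rod-shaped bacteria
    from epifluorescence z-stacks. Implements autofluorescence-based cell
    segmentation with a newborn-cell size filter, diffraction-limited spot
    detection (maximum projection, band-pass filtering, windowed local-maximum
    peak calling), photobleaching-step analysis to verify single-fluorophore
    detection, and intensity-based concentration quantification. A
    spherocylinder Monte-Carlo simulator quantifies diffraction-limited
    undercounting (Poisson copy numbers, 2D projection, eps-clustering), and a
    synthetic microscopy generator provides ground-truth images so the whole
    pipeline is verifiable without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
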