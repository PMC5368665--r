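Package: microwellflux
Title: Single-Cell Oxygen Consumption and Extracellular Acidification from
    Sealed Microwell Fluorescence Time-Lapse Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of sealed microwell array bioenergetics
    assays: detection and tracking of hexagonally packed microwells in
    multi-channel fluorescence time-lapse stacks, coefficient-of-variation
    image quality control, seal-integrity classification from a terminal
    oxygen-purge phase, Stern-Volmer oxygen sensor and sigmoid pH sensor
    calibration, per-well and per-cell oxygen consumption rate (OCR) and
    extracellular acidification rate (ECAR) estimation by linear regression,
    nuclei counting for per-cell normalization, and population-level
    statistics. Includes a forward-model synthetic assay generator that
    renders complete image stacks with ground truth so every stage of the
    pipeline can be validated without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    tiff,
    jsonlite,
    yaml,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CellBiology, SingleCell, Metabolomics, QualityControl, Software
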