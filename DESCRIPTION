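Package: stomataMorph
Title: Stomatal Morphometry from Epidermal Micrographs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for high-throughput stomatal phenotyping of grass
    (maize-type) abaxial epidermis micrographs. Provides a reproducible
    synthetic epidermis generator with exact analytic ground truth, a
    pluggable detector/segmenter contract with classical reference
    implementations, fusion of stomatal-complex and guard-cell-and-pore
    semantic masks, connectivity-based extraction of individual stomatal
    complexes, the eleven standard density/size/shape traits (SD, SW, SL,
    SA, SP, GCPA, SCA, SR, SE, PGCPA, PSCA), detection and segmentation
    accuracy metrics (precision, recall, AP50, GIoU loss, Dice, IoU,
    reliability regression), and the downstream statistical layer
    (Pearson correlation matrices, one-way ANOVA with compact letter
    display, z-score PCA, and mid-/over-parent heterosis rates for
    hybrid-versus-parent comparisons).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    grDevices,
    utils,
    EBImage,
    png,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    multcomp,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'annotations-io.R'
    'calibrated-image.R'
    'detection.R'
    'metrics-detection.R'
    'metrics-segmentation.R'
    'segmentation.R'
    'morphometry.R'
    'pheno-stats.R'
    'reference-data.R'
    'synthetic-scene.R'
    'utils.R'
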