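Package: stromascope
Title: Stromal Composition Quantification for Multiplexed IHC Tissue Microarray Cores
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies tumor-stroma composition from multiplexed
    immunofluorescence (mfIHC) and chromogenic IHC images of prostate tissue
    microarray (TMA) cores, and relates stromal marker fractions (FAP, SMA,
    CD8, CD163) to lesion class and patient outcome. Provides two-round DAPI
    registration, adaptive Otsu tissue/epithelium/stroma/lumen/nuclei
    segmentation, random-forest pixel classification for brightfield
    FAP/SMA/hematoxylin stains, per-core and per-patient quantification, and
    the accompanying statistical layer (group comparisons, correlations,
    dichotomization, Bonferroni-corrected univariable Cox screens,
    Kaplan-Meier/log-rank, proportional-hazards diagnostics, and DeLong ROC
    comparison). A synthetic-data module generates misregistered two-round
    core images with ground-truth masks and survival cohorts with known
    statistical structure, so that every stage is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    graphics,
    jsonlite,
    nortest,
    ranger,
    stats,
    survival,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
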