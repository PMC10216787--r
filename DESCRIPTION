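Package: organoscreen
Title: Image-Based and Viability-Based Drug Testing in Tumor Organoids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for medium-throughput drug testing in 3D tumor
    organoid cultures read out by high-content live-cell confocal imaging and
    by whole-well viability assays. Segments organoids from the combined
    three-channel fluorescence image (Hoechst 33342, Caspase 3/7 Green,
    propidium iodide) on individual z-planes, excludes sub-250 um^2 debris,
    segments nuclei within organoids and extracts per-nucleus dye
    intensities. A control-calibrated gating model classifies every nucleus
    as viable, apoptotic, necrotic or late-apoptotic from straight gate
    lines anchored at the mean + 2 SD viable-intensity thresholds.
    Organoid-load statistics (nuclei counts, mean organoid size, organoid
    counts) are normalized to day-0 baseline and compared between treated
    and untreated wells. The viability arm provides vehicle normalization,
    four-parameter logistic dose-response fitting, and plate acceptance
    rules (growth ratio, coefficient of variation, Z-factor, DMSO effect).
    A seeded synthetic-data generator renders ground-truth-labelled
    three-channel z-stacks and viability plates so every stage is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    EBImage,
    graphics,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
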