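Package: drgCalcium
Title: Responder Analysis for In Vivo Sacral DRG Calcium Imaging
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for in vivo epifluorescence calcium imaging of
    sacral dorsal root ganglia during a seven-episode colonic and perineal
    mechanical stimulation protocol. Extracts annulus ("donut") background
    corrected percent dF/F traces from registered movie stacks and ROI label
    images, calls per-episode responders at a strict dF/F threshold, applies
    exclusion rules (spontaneous baseline activity, persistent activation,
    overlapping ROIs, mixed internal/external responses), classifies cells as
    internal, external-gentle or external-noxious responders, pools responder
    proportions and compares groups with a chi-square test, and renders
    pixelwise standard-deviation spatial activity maps and category-sorted
    heatmap layouts. A ground-truthed synthetic movie generator emulating
    GCaMP6f-like transients makes every stage testable without recordings,
    and companion helpers compute gastrointestinal quantification ratios
    (gastric emptying, nerve density, intraganglionic varicose ending
    density, stool water content).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tools,
    S4Vectors,
    SummarizedExperiment,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pheatmap
biocViews: Software, CellBasedAssays, Visualization, Preprocessing
Config/testthat/edition: 3
RoxygenNote: 7.3.3
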