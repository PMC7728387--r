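Package: phenoscope
Title: Quantitative Phenomic-Screen Microscopy Pipeline for Yeast GFP Collections
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates and quantifies high-content fluorescence microscopy
    screens of GFP-fusion yeast strains. Generates calibrated synthetic
    multi-channel z-stack fields with known per-cell ground truth
    (cytoplasmic, nuclear, punctate, mitochondrial and cell-periphery
    localization classes), segments cells from brightfield, measures
    per-cell mean GFP intensity and paired mutant/wild-type fold changes
    with fixed hit cut-offs and two-round confirmation, performs 3D
    mitochondrial voxel morphometry (volume, surface area, skeleton
    features) and strain-level mitochondrial fractions, extracts
    nucleus-centered line profiles and classifies localization changes
    into six categories, and provides growth-curve doubling time, delta
    delta Ct expression, normalization helpers and the shared
    t-test/ANOVA+Tukey machinery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    EBImage,
    igraph,
    stats,
    tiff,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
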