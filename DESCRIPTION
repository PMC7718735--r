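Package: mythquant
Title: Quantification of Arrayed Membrane Yeast Two-Hybrid Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Image-based quantification of arrayed split-ubiquitin
    membrane yeast two-hybrid (MYTH) screens. Provides plate-grid
    detection and per-spot colony density extraction from test-plate
    photographs, diploid colony-area normalization, calibration of a
    positive-interaction density cutoff from manually labeled colonies,
    majority-rule interaction calling over technical quadruplicates,
    cross-bait and replicate comparison (shared hits, fold enrichment,
    Venn partitions, hypergeometric term enrichment with Bonferroni
    correction, hierarchical clustering), and a nuclear-envelope GFP
    quantification pipeline (rolling-ball background subtraction,
    automatic thresholding, particle filtering by area and circularity,
    per-nucleus mean intensity on sum projections). Includes synthetic
    plate-image and confocal z-stack generators with known ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
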