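Package: binatlas
Title: Cross-Dataset Label-Free Proteomics Integration via Rank Bins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-search processing for label-free proteomics protein-group
    tables: contaminant/decoy/PSM filtering, fraction-of-total (FOT)
    normalization to parts per billion, collapsing of protein groups to
    canonical genes, batch-wise rank binning for cross-dataset comparison,
    organ-specificity classification (organ-enriched, group-enriched,
    mixed), decoy-based cross-dataset false discovery rate estimation, and
    comparison statistics against categorical and continuous reference
    atlases (randomized edit distance difference, set overlap, log2-median
    correlation). Includes a synthetic multi-dataset generator with known
    ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
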