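Package: rtmis
Title: Targeted RT-MLPA Sequencing Analysis for B-Cell Lymphoma Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end analysis of ligation-dependent RT-PCR (RT-MLPA)
    sequencing assays for non-Hodgkin B-cell lymphoma diagnostics: probe-panel
    management, read-to-probe matching with UMI-based molecular counting,
    depth-invariant expression normalization, a seven-class random-forest
    subtype predictor with per-class vote probabilities, differential
    expression and PCA summaries, and survival analyses including
    expression-threshold scanning and double-expressor calling. Includes a
    synthetic-data generator emulating subtype-structured marker counts,
    read-level UMI/error structure and survival outcomes, so the whole
    pipeline can be exercised without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ranger,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
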