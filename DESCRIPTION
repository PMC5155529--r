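Package: breathomics
Title: Neonatal Respiratory Waveform Analysis and Regulatory Omics Integration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for neonatal head-out pneumotachography and
    transcription-factor dosage studies. Integrates pneumotachograph flow
    traces into calibrated volume waveforms, segments breaths, and computes
    ventilation (respiratory rate, tidal volume, minute ventilation) and
    breathing-pattern statistics (apnea detection on interbreath intervals,
    coefficient-of-variation instability measures, Poincare pairs).
    Implements microarray-style differential expression (pooled two-sample
    t-tests with Benjamini-Hochberg false discovery rate control and signed
    fold-change thresholds), delta-delta-Ct qPCR quantification,
    hypergeometric gene-set overlap and reciprocal-deregulation tests
    between gain- and loss-of-function studies, and GREAT-style
    basal-plus-extension assignment of ChIP-seq peaks to genes. A synthetic
    data module generates all pipeline inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml,
    limma,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
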