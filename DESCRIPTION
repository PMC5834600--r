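Package: lyoscreen
Title: Plate-Based Flow-Cytometry Surface-Protein Screening of Barcoded
    Cell Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An end-to-end pipeline for high-throughput surface-protein
    screening of two fluorescently barcoded cell populations pooled into
    96-well antibody-panel plates and read by flow cytometry. Provides a
    synthetic list-mode plate simulator with planted ground truth, a
    minimal FCS 3.1 reader/writer, event-level gating (debris, doublet,
    viability and barcode demultiplexing gates, isotype-referenced
    positivity gates), marker-level screening statistics (percent
    positive, fold increase, one-way ANOVA, stain index with robust
    background correction, delta-delta-Ct), and profile-level summaries
    (PCA, hierarchical clustering, report rendering).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    MASS,
    stats,
    utils,
    grDevices,
    ggplot2,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
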