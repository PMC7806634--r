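Package: chondronet
Title: Off-Target Lineage Discovery and Heterocellular WNT Signaling in
    hiPSC Chondrogenesis Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested single-cell RNA-seq analysis pipeline for directed
    hiPSC chondrogenesis pellet cultures: barcode calling and cell/gene
    quality control, depth normalization, highly variable gene selection,
    cell-cycle scoring and covariate regression, shared-nearest-neighbor
    modularity clustering with thresholded marker detection, weighted gene
    co-expression network construction (signed adjacency, topological
    overlap, module detection with eigengene merging), transcription-factor
    anchored regulatory subnetworks with three-component hub-gene scoring,
    and a directed ligand-receptor model of population-to-population
    signaling. Ships a ground-truthed negative-binomial UMI simulator that
    emulates day-14 pellet composition (chondrocytes, neural cells,
    melanocytes, mesenchyme) with population-restricted WNT ligands, FZD
    receptors, planted co-expression modules, low-quality cells, doublets,
    and two-species barnyard mixtures, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    stats,
    utils,
    methods,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
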