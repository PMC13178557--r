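Package: engramprot
Title: Statistical Analysis of Engram-Synapse Proteomic and Imaging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for sorted-synaptosome proteomics of memory
    engram cell synapses and associated imaging readouts. Computes paired
    within-mouse differential-expression effect sizes with
    Benjamini-Hochberg FDR control, fits a robust Huber regression of
    context-exploration on fear-conditioning effect sizes to classify
    condition-dominant proteins with bootstrap prediction intervals, tests
    the association of dominance with synaptic compartment (chi-square,
    Kolmogorov-Smirnov, logistic odds ratios, gene-set enrichment),
    performs quadrant gating and colocalization statistics on two-marker
    synaptosome intensities, and registers 3D fluorescence puncta to
    traced dendritic spines with cluster-bootstrap colocalization odds
    ratios. A seeded synthetic-data generator emulates the statistical
    structure of every input so the full pipeline runs without external
    data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
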