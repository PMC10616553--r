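Package: phosflow
Title: Kinase Signaling Network Inference from TMT Phosphoproteomics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for inferring kinase signaling
    networks from isobaric (TMT) phosphoproteomics screens of drug-perturbed
    cell lines. Converts PSM-level reporter-ion intensities to normalized
    protein and phosphosite log2-ratio matrices (reference-channel ratios,
    recursive Dixon outlier removal, median rollup, two-component
    Gaussian-mixture mode alignment, trimmed scaling, metric MDS), computes
    moderated-t differential statistics with Benjamini-Hochberg correction and
    protein-abundance adjustment of phosphosites, infers site-specific causal
    kinase-substrate networks from a signed prior with label-randomization
    protein-activity calls across an FDR sweep, and scores directional PTM
    site signatures with a weighted running-sum enrichment statistic. A
    synthetic-data module generates prior networks, planted kinase
    perturbations and TMT-like reporter tables with known ground truth so
    every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    limma,
    stats,
    tibble,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
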