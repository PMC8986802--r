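Package: sctem
Title: Single-Cell Transposable Element Methylation Sequencing Toolkit
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of single-cell transposable element
    methylation sequencing (scTEM-seq), an amplicon bisulfite assay that
    estimates global DNA methylation of a cell from thousands of SINE Alu
    loci at ~20,000 reads. Provides a synthetic TE reference and 96-well
    combinatorial dual-index primer-plate model, a read simulator with
    ground truth (bisulfite conversion failure, methylation-dependent
    amplification bias, sequencing error), internal dual-index
    demultiplexing, three-letter bisulfite alignment with CpG/CHG/CHH
    methylation extraction to Bismark-style coverage files, per-cell
    site-mean methylation estimation with TE-annotation QC, depth
    down-sampling stability analysis, tiled bulk comparison, and
    correlation of methylation with gene and TE-family expression under
    Benjamini-Hochberg FDR control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    Biostrings,
    IRanges,
    S4Vectors,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
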