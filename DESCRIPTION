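Package: cogex
Title: Clusters of Gene Expression Analysis for Stepwise Tumor Progression Series
Version: 0.1.0
Authors@R:
    person("cogex", "maintainers", email = "cogex@example.org", role = c("aut", "cre"))
Description: Downstream transcriptomic analysis of an ordered tumor-progression
    cell-line series from FPKM expression matrices. Calls differentially
    expressed genes between successive parental/derived lines with per-gene
    Student t-tests and Benjamini-Hochberg false discovery rate correction,
    classifies genes into the 11 clusters of gene expression (CoGE) taxonomy
    using fold-change thresholds, scores the absolute and relative contribution
    of each cancer hallmark to a reference hallmark (invasion and metastasis)
    through pathway and gene-set overlaps, and detects progression-consistent
    biomarker genes. Includes a synthetic-data generator with known ground
    truth, strict readers and writers for the expression/GMT/annotation file
    formats, worked-example fixtures, and a command-line pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
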