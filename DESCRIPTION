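Package: dropquant
Title: Droplet Single-Cell RNA-Seq Quantification via Parsimonious UMI Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@dropquant.dev", role = c("aut", "cre"))
Description: End-to-end quantification of droplet-based single-cell RNA-seq
    (dscRNA-seq) experiments from demultiplexed FASTQ files. Implements cell
    barcode whitelisting by kernel-density knee detection, one-edit barcode
    correction, stranded k-mer pseudo-mapping to transcript equivalence
    classes, UMI deduplication by greedy covering of a parsimonious UMI graph
    with monochromatic arborescences (with an exact small-instance solver as
    an oracle), EM resolution of gene-ambiguous molecules, per-gene evidence
    tiers, optional per-cell bootstrap variances, and a naive-Bayes final
    whitelist. Ships a droplet-protocol simulator (transcriptome, PCR,
    fragmentation, sequencing error, ambient barcodes) emitting FASTQ plus
    ground truth, so the whole pipeline is testable in a closed loop.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Matrix,
    data.table,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    e1071,
    optparse
Config/testthat/edition: 3
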