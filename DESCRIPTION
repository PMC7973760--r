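Package: ddradtools
Title: Design and Diagnostics for Double-Digest RAD Sequencing Platforms
Version: 0.1.0
Authors@R:
    person("San Pedro", "Genomics Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for fine-tuning a double-digest restriction-site-associated
    DNA sequencing (ddRAD-seq) genotyping platform: in silico single and double
    restriction digestion with fragment end-type classification, size-selection
    window optimization and enzyme-pair ranking, sequencing yield and depth
    planning, coverage-overlap diagnostics for multiplexed libraries (breadth
    and depth of coverage, fixed-width bin count matrices, sample correlation
    and clustering, principal component analysis, per-pool common sites and
    artificial-pool batch-effect tests), and multi-sample variant
    summarization (microsatellite detection with MISA-style thresholds,
    transition/transversion ratios, insertion/deletion statistics,
    variant-sharing distributions, minor-allele-frequency and missingness
    filtering, and per-window variant density). A seeded synthetic-data module
    generates genomes, alignments and genotype matrices with the statistical
    structure these analyses assume, so the whole pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    jsonlite,
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    Rsamtools,
    GenomicAlignments,
    VariantAnnotation,
    SummarizedExperiment,
    withr,
    optparse
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
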