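Package: promscreen
Title: Mining Condition-Specific and Constitutive Bacterial Promoters from
    Comparative Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to identify candidate condition-specific and constitutive
    promoters in bacteria from replicated comparative RNA-seq experiments.
    Implements TPM normalization, pairwise differential statistics with
    log2 fold-change and expression filters, distance-based operon inference
    with operon-head resolution, dual top-k candidate selection plus
    paralogous-operon deduplication, strand-aware extraction of upstream
    intergenic regions, reporter-assay fold-ratio classification, and
    delta-delta-Ct relative quantification. A seeded synthetic-data module
    simulates an annotated multi-replicon genome with planted differential
    expression so every stage can be benchmarked against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    Biostrings,
    GenomicRanges,
    GenomeInfoDb,
    BiocGenerics,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
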