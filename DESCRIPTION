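Package: mirtas
Title: Cataloging and Prioritizing Trait-Associated Variants in the
    microRNA Regulome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An integrative pipeline for cataloging and prioritizing
    trait-associated single nucleotide polymorphisms (TASs) in the
    microRNA regulome. Expands GWAS index SNPs into population-matched
    linkage-disequilibrium blocks from phased haplotype panels, predicts
    seed-based miRNA target sites (7mer-1a, 7mer-m8, 8mer-1a) on
    reference and allelic-complement 3'-UTR sequences, calls
    created/abolished sites, tiers candidates against competing
    functional annotations, and tests miRNAs as candidate regulatory
    hubs in trait gene networks by Monte Carlo simulation. Includes
    deterministic synthetic-fixture generators so the full pipeline is
    testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    BiocGenerics,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer,
    SummarizedExperiment,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
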