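Package: circPipe
Title: Consensus Detection, Conservation and Functional Screening of
    Circular RNA Backsplice Junctions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of circular RNA (circRNA) backsplice
    junction calls from bulk total RNA-seq. Merges the junction tables of
    two detection tools into a consensus set with expression-pattern
    filters, annotates candidates against gene models (host genes,
    exon-intron boundary concordance, exon content), classifies
    cross-species backsplice conservation by lifting splice sites through
    a UCSC chain file and comparing them to a circRNA database, screens
    candidate miRNA sponges with a seed-anchored duplex scanner, performs
    SRPBM-normalized Kruskal-Wallis differential expression with
    Benjamini-Hochberg correction, and runs Fisher term enrichment of
    host genes against an expressed-gene background. Includes seeded
    synthetic-data generators with planted ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    withr,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
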