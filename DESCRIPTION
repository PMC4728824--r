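Package: MotifTargets
Title: Region-Aware Scanning of Transcription-Factor Binding Motifs and
    Primary-Target Calling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Scans annotated genomes for transcription-factor binding
    motifs given as IUPAC-degenerate strings or position weight matrices,
    restricted to user-selected gene regions (5'/3' intergenic flanks,
    UTRs, coding exons, introns) with intergenic windows truncated at
    flanking coding sequence. Per-locus site counts are scored against a
    genome nucleotide background model (Motif Score, cumulative binomial
    p-value). Expression fold-change tables are integrated to compute
    Binding Scores and chi-squared enrichment for discriminating primary
    from secondary target genes, and file-backed interaction networks
    provide interactor neighborhoods for the called targets. A
    deterministic synthetic-fixture generator with planted sites supports
    validation end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
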