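Package: orphanscan
Title: Taxon-Scoped Homology Cascade for Orphan Gene Identification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies species-specific orphan genes, lineage-specific genes,
    and evolutionarily conserved genes in a focal plant genome by running a
    two-phase homology-evidence cascade over taxon-scoped BLAST tabular hit
    tables, with full per-stage provenance and tallies. Also computes genic
    feature statistics (gene/CDS/intron lengths, GC content, exon counts,
    chromosome distribution and physical maps), tissue- and stage-specific
    expression calls from FPKM matrices, and relative qPCR expression via the
    2^-ddCt method with ANOVA and compact letter displays. Ships a built-in
    seed-and-extend similarity search and a planted-truth synthetic-data
    generator so the whole pipeline is testable without external databases.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    data.table,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
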