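Package: cas9tiler
Title: Design and Evaluation of Cas9-Targeted Nanopore Enrichment Panels
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for amplification-free targeted long-read sequencing of
    a genomic locus by CRISPR-Cas9 excision. Scans a reference sequence for
    SpCas9 guide candidates (20-nt protospacer + NGG PAM) and scores them
    (GC content, hairpin self-complementarity, mismatch-tolerant off-target
    counts, cut-efficiency surrogate); selects opposite-strand guide pairs
    tiling a locus in ~10 kb blocks and arranges them into "bricklayer" or
    "highway" reagent pools; simulates cut-initiated nanopore reads with
    lognormal lengths and per-read quality; computes coverage QC (per-base
    depth, cumulative coverage, read N50) and compares two variant callsets
    (concordance, genic-region classification, rarity filter). Includes a
    seeded synthetic-fixture generator so the whole pipeline runs without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    BiocGenerics,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    optparse,
    methods,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
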