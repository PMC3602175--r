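Package: chlorocomp
Title: Comparative Genomics of Chloroviruses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative genomics of large double-stranded DNA
    viruses of the genus Chlorovirus: reading and writing annotated genomes
    (GenBank flat files or FASTA/GFF3 pairs), construction of orthologous
    protein families by reciprocal best hits with single-linkage clustering
    and in-paralog assignment, classification of families into core,
    host-specific, opposite-pattern, scattered and singleton categories,
    parsimony reconstruction of the ancestral gene repertoire, detection of
    compositionally deviant (putatively horizontally transferred) genes with
    a codon-position-specific Markov model and a compositional deviation
    index (CDI), gene-order dot-plots with colinear-block detection and
    reference-guided contig ordering, plus a synthetic-genome generator with
    full ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    S4Vectors,
    igraph,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
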