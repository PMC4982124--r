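Package: familyscope
Title: Genome-Wide Identification and Evolutionary Annotation of
    LRR-RLK Gene Families
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genome-wide identification and
    evolutionary annotation of plant leucine-rich-repeat receptor-like
    kinase (LRR-RLK) gene families. From domain-annotated proteomes it
    retrieves kinases, transmembrane kinases and LRR-RLKs, extracts and
    merges kinase-domain units, builds filtered kinase-domain alignments,
    estimates neighbor-joining phylogenies with bootstrap support,
    assigns subfamily groups (I-XVI, with the XIIa/XIIb split) by
    co-clustering with labelled reference sequences, classifies RD versus
    non-RD catalytic loops, detects tandem-duplication clusters within
    200 kb windows, identifies orthologs by bidirectional best hits with
    clade confirmation, and locates syntenic blocks by exact-anchor
    chaining. A synthetic two-species genome simulator with a
    machine-readable truth table supports end-to-end validation of every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    GenomicRanges,
    jsonlite,
    rtracklayer,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
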