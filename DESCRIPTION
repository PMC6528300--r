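Package: plastanno
Title: Reference-Based Plastid Genome Annotation by Homology Transfer
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Batch annotation of unannotated plastid genomes (plastomes) by
    homology transfer from annotated GenBank reference plastomes. Reference
    genes are used as queries against the target sequence (reverse
    query-subject search); preliminary high-scoring segment pairs are then
    refined with a gene boundary detection algorithm (start/stop codon
    resolution for protein-coding genes, probe-based end refinement for RNA
    genes), an intron boundary detection algorithm (exon-intron boundary
    placement, split-codon arithmetic and intron-loss detection), inverted
    repeat detection by self-alignment, and query-coverage pseudogene
    screening. Emits annotated GenBank flat files and a structured warning
    log, and ships a synthetic plastome fixture generator with known-truth
    annotations for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    BiocGenerics,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Annotation, Alignment, SequenceMatching, Genetics
Config/testthat/edition: 3
RoxygenNote: 7.3.3
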