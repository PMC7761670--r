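Package: rdnaContacts
Title: Whole-Genome 4C Contact Analysis for an rDNA Viewpoint
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: An end-to-end analysis pipeline for whole-genome chromosome
    conformation capture (4C) data anchored at the ribosomal DNA cluster.
    Provides contact-track calling from mapped-read coverage (replicate
    intersection with value averaging, repeat-containment filtering, read
    thresholding, resolution-based extension), gene assignment and
    contact-gene list construction, replicate concordance checks on binned
    RPKM coverage, negative-binomial differential analysis of contact and
    expression count tables, genomic-feature and 9-state chromatin
    annotation of contact sites with permutation-based enrichment nulls
    (three segment-shuffling schemes), gene-list overlap resampling,
    viewpoint proximity checks, and signal metaprofiles around contact
    sites. A synthetic-data module generates a miniature genome with
    planted contact genes, differential effects, and chromatin-state
    enrichment so the whole pipeline can be exercised against known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
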