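Package: retroscape
Title: Comparative Analysis of Transposon Landscapes in Orthologous Genomic Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative analysis of orthologous genomic regions
    shaped by LTR-retrotransposon activity: a synthetic region-evolution
    simulator with a replayable truth log, BAC-end-sequence anchoring of
    orthologous clones, colinearity-block construction with target-site-
    duplication (TSD) polarization of transposon insertions, Kimura
    two-parameter dating of insertions and duplications from LTR or paralog
    divergence, neighbor-joining phylogenies of duplicated genes and of
    binary insertion-polymorphism markers, gene gain/loss parsimony scenario
    scoring, and population-level in-silico genotyping of insertion
    junctions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    rtracklayer,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
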