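Package: phaseprint
Title: Intron-Phase Fingerprinting and Duplication-Origin Analysis for
    Gene Families in Allopolyploids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analyses the evolution of a transcription-factor gene family in
    an allotetraploid genome. Reconstructs gene models from FASTA/GFF3,
    computes intron insertion sites and splicing phases in CDS and protein
    coordinates, fingerprints a conserved domain (the K-box of MIKC MADS-box
    proteins) by its ordered intron-site/phase signature and clusters the
    signatures into conserved patterns, builds neighbor-joining phylogenies
    (p-distance, pairwise deletion, bootstrap) and tests clade-pattern
    concordance, classifies the origin of each family member in an
    allopolyploid (progenitor-inherited, tandem, segmental, homoeologous
    exchange) from reciprocal-best-hit synteny, scans promoters against an
    IUPAC cis-element catalog, and scores expression-profile conservation of
    sister paralog pairs. Ships a deterministic synthetic allotetraploid
    generator with truth tables for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    pheatmap
Config/testthat/edition: 3
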