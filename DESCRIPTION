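Package: zfam
Title: Gene-Family Characterization Toolkit for C4-Type Zinc Finger Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis toolkit for characterizing a gene family across small
    animal genomes, built around the C4-type zinc finger (nuclear hormone
    receptor) family of tardigrades. Provides a synthetic-genome generator with
    a verifiable truth ledger; domain-distribution census statistics (m, M,
    p = m/M) and superkingdom-exclusivity calls; multi-evidence family
    identification with domain validation; strand-aware promoter extraction and
    IUPAC degenerate-consensus cis-element scanning from JASPAR position
    frequency matrices; MCScanX-style duplicate-gene classification (tandem,
    proximal, dispersed, singleton); hypergeometric enrichment with
    Benjamini-Hochberg correction and signed log10 scores; Nei-Gojobori (1986)
    Ka/Ks with Jukes-Cantor correction and codon bootstrap; phylostratigraphic
    gene-age assignment; physicochemical protein properties; outgroup rooting
    and anchor-based clade grouping; and cross-stage integration with
    differential-expression tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    ape,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    seqinr,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
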