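Package: famscan
Title: Gene-Family Identification and Molecular Evolution Toolkit for
    Plant Cyclic Nucleotide-Gated Channels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An offline pipeline for genome-wide surveys of the plant
    cyclic nucleotide-gated channel (CNGC) gene family and similar ion-channel
    families. Implements PROSITE-dialect motif compilation and scanning with the
    plant CNGC-specific phosphate-binding cassette/hinge motif, candidate
    identification with length and redundancy filters, protein physicochemical
    characterization (molecular weight, theoretical isoelectric point, GRAVY),
    Nei-Gojobori (1986) Ka/Ks estimation with Jukes-Cantor correction and
    synonymous-rate divergence dating, exact spliced inference of exon-intron
    structure from CDS and genomic sequence with intron phases, IUPAC
    cis-regulatory element scanning of promoters against PLACE-style tables,
    neighbor-joining phylogenies from Poisson-corrected protein distances with
    bootstrap supports and clade-based group assignment, FPKM tissue-specificity
    summaries, and seeded synthetic-data generators that emulate each input so
    the whole pipeline is testable without genome downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    ape,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    seqinr,
    jsonlite,
    withr
Config/testthat/edition: 3
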