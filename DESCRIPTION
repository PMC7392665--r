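Package: utr3frame
Title: Discovery and Characterization of Splicing-Accessible Coding 3'UTRs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies transcripts in which skipping of the penultimate exon
    induces a frameshift that moves the stop codon into the last exon and
    extends translation into the annotated 3'UTR, escaping nonsense-mediated
    decay. Provides junction-read percent-spliced-in (PSI) quantification with
    expression and alternative-splicing filters, amino-acid composition and
    SH3-binding proline-rich (PxxP) motif frequency scoring of the alternative
    C-termini, proline-delta stability grouping against protein half-life
    tables, three-frame last-exon ORF scanning for cross-species comparison,
    hypergeometric ortholog-overlap testing, and construction of
    frameshift-augmented protein search databases with in-silico tryptic
    digestion and proteotypic-peptide flagging. A synthetic-data module
    generates toy genomes, junction counts and half-life tables with planted
    truth so every stage is testable without external downloads.
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
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
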