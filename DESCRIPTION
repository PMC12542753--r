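Package: virotime
Title: Temporal Dissection of Lytic Virus Infection Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for dissecting the transcriptional program of a lytic
    virus infection time course from strand-specific RNA-seq coverage:
    RPKM/percent-of-maximum temporal profiles and half-maximum
    classification of viral genes into early, middle, middle-down and
    late groups; transcription start site (TSS) detection from
    replicated coverage step-changes with sense/antisense/internal
    orientation; assembly of genes into transcriptional units (operons)
    from gap, co-expression and coverage-continuity criteria with
    internal-promoter-driven splitting; antisense-dominated gene
    calling; and functional-category (arCOG-style) fold over- and
    underrepresentation of host differentially expressed genes. A
    seeded synthetic-data generator plants ground-truth classes, TSSs,
    operons, antisense transcripts and host DEGs so every stage can be
    validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
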