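Package: erfminer
Title: Genome-Wide AP2/ERF Family Identification, Molecular Evolution and
    Ripening Expression Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for genome-wide identification and classification of
    AP2/ERF transcription factors from domain architecture and a labeled
    reference panel, detection of C-terminal activation/repression motifs
    (EAR, R/K-LFGV, EDLL), gene-structure and intron-richness analysis from
    GFF3, tandem/segmental duplication classification, Nei-Gojobori (1986)
    Ka/Ks estimation with Jukes-Cantor correction and divergence-time dating,
    promoter extraction with cis-regulatory element scanning, and a
    three-dataset expression screen (FPKM/TPM normalisation, tissue-dominance
    and ripening-correlation ratio rules, fold-change DEG calling, and the
    cross-dataset intersection that nominates key ripening regulators).
    Includes deterministic synthetic-data generators with planted ground
    truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
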