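Package: venomics
Title: Integrated Transcriptomic and Proteomic Identification of Parasitoid Venom Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A proteogenomic pipeline for identifying the secreted venom
    proteins of a parasitoid wasp venom gland from an assembled
    transcriptome and a mass-spectrometry peptide list. Contigs are
    translated in all six reading frames into a protein database, observed
    tryptic peptides are mapped back onto the translations, candidates are
    filtered to a signal-peptide-bearing secretome, validated by exact
    local alignment against a reference venom-protein set, and
    complemented by an annotation keyword search. Expression is quantified
    by RPKM and efficiency-corrected relative qPCR, venom-associated GO
    terms are detected by Fisher's exact enrichment with FDR control, and
    a stage-by-stage count ledger enforces the arithmetic identities
    linking the sets. A fully ground-truthed synthetic venom-gland study
    generator makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    stats,
    utils,
    methods
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
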