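Package: bargap
Title: Barcode-Gap Characterisation, Distance-Threshold Species
    Delimitation and Diagnostic-Indel Detection for DNA Barcodes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the molecular side of integrative taxonomy with
    CO1 (COI) DNA barcodes: uncorrected pairwise distances under explicit
    gap/ambiguity policies, per-species molecular characterisation
    (IUPAC majority consensus, maximum intraspecific and minimum
    interspecific barcode distances), objective clustering at a fixed
    distance threshold with ranked barcode-gap partitions, congruence
    classification of molecular partitions against reference species
    labels, and codon-aware detection of clade-diagnostic in-frame
    deletions under the invertebrate mitochondrial genetic code. A
    Jukes-Cantor simulator generates labelled barcode datasets with a
    controlled barcode gap so every stage of the pipeline can be
    exercised and calibrated without external data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
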