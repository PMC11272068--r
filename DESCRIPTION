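Package: compcode
Title: Protein Identification from Residue Composition Codes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts protein and peptide sequences into residue composition
    codes (relative counts of chemically labelable residue types such as Cys,
    Lys, Met, Asp/Glu, Tyr, Arg, His, Trp and Ser), builds searchable code
    libraries from proteomes or secretomes, and identifies measured codes by
    cosine-similarity ranking. Includes noise-free and Monte Carlo evaluation
    of top-N identification coverage under Gaussian relative measurement
    error, conversion of qPCR threshold-cycle (Ct) measurements into
    composition codes via fitted standard curves, extraction of secreted
    mature chains from UniProt-style annotation, and seeded synthetic
    proteome and measurement generators for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
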