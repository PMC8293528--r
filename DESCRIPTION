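Package: residuefinder
Title: Regular-Expression Mining of Amino Acid Residue and Point-Mutation
    Mentions in Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts mentions of individual amino acid residues (e.g. "Ser56",
    "S 56", "serine 56") and point mutations in wNm nomenclature (e.g. "A64G")
    from plain-text scientific articles using selectable regular-expression
    libraries.  Ships the full residue-mention libraries together with reduced
    ("cut") variants that trade a small loss of recall for a several
    hundredfold reduction in the number of expressions scanned.  Includes a
    precision/recall/F-beta evaluation harness against gold-standard
    annotation files, bibliography stripping, unique-mention and full-count
    reporting, and a deterministic synthetic-corpus generator that plants
    residue mentions across nomenclature variants alongside classed distractor
    text (motif names, equipment, bibliographies, chemical formulas) so that
    extraction behaviour is testable without access to licensed article
    corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    stringi,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
VignetteBuilder: knitr
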