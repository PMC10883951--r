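Package: sdsindex
Title: Automated Indexing of Chemical Composition from Safety Data Sheets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: A multi-stage pipeline that extracts structured composition
    information (ingredient names, CAS registry numbers, and weight
    percentages) from Safety Data Sheet (SDS) documents in PDF form.  The
    pipeline chains a no-data filter, rule-based composition-page selection,
    table/section region detection, text-based table structure extraction,
    and regex- plus recognizer-driven ingredient record assembly, and ships
    a tiered (entity / record / document) precision-recall evaluation
    harness together with a seeded synthetic-SDS generator that renders
    text-based PDFs with complete gold standards so every stage is testable
    without proprietary data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    glmnet
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
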