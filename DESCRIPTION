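Package: schemakit
Title: Schema Modeling Kernel for FAIR Sample Metadata
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A self-contained schema-modeling kernel for FAIR (Findable,
    Accessible, Interoperable, Reusable) scientific metadata, exercised on
    microbiome sample metadata. Schemas are authored in YAML or as
    spreadsheet-style tables with a directive row, compiled into an induced
    view that resolves class inheritance and slot overrides, and used to
    validate instance data against types, patterns and controlled
    vocabularies. Downstream artifacts -- JSON Schema (draft 2020-12),
    Markdown documentation with a class-relationship edge list, and minimal
    SQL DDL -- are generated from the compiled view. Additional tooling
    includes a configurable schema linter, a declarative schema/data
    transformation engine (rename, split, merge, retype, recardinalize,
    subset), CURIE/URI prefix machinery, and a synthetic messy-spreadsheet
    generator with a harmonization pipeline for end-to-end demonstrations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    DBI,
    RSQLite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
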