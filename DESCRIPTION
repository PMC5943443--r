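Package: taxotables
Title: Relational Management of Taxonomic Checklists
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An S4 data model for taxonomic lists that separates taxon usage
    names, taxon concepts, taxon views and taxon traits into four linked
    tables, with an exhaustive validity-rule engine, hierarchy-aware editing
    and querying (parent-child relationships over a user-defined rank
    ladder), import of flat synonymy tables and of Turboveg-dialect species
    lists (DBF), a zip-of-CSV archive format and timestamped backups. Built
    for cleaning, querying and versioning floristic checklists
    reproducibly, e.g. species lists behind vegetation-plot databases.
License: GPL-3
Encoding: UTF-8
Depends:
    R (>= 4.0),
    methods
Imports:
    utils,
    stats,
    jsonlite,
    zip
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'AllClasses.R'
    'accessors.R'
    'summary.R'
    'validation.R'
    'edit.R'
    'query.R'
    'flat.R'
    'dbf.R'
    'turboveg.R'
    'archive.R'
    'fixtures.R'
    'cli.R'
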