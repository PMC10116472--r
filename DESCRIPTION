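Package: schemaforge
Title: Authoring, Validating, Comparing, and Registering Class-Based
    Biomedical Metadata Schemas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for working with class-based biomedical metadata schemas
    expressed as JSON-LD documents with embedded JSON Schema validation rules.
    Supports parsing and canonical serialization of RDF-Schema-style documents,
    class-hierarchy construction with multi-parent property inheritance,
    non-interactive extension of existing classes (for example extending the
    Schema.org Dataset class with new properties such as infectiousAgent),
    marginality (required/recommended/optional), cardinality (one/many) and
    ontology-identifier value constraints, instance-document validation and
    example-markup generation, a file-backed searchable schema registry rooted
    in a bundled Schema.org core snapshot, and shared/unique property
    comparison across two to four classes. Ships a reconstruction of the
    multi-class COVID-19 Outbreak schema as a worked fixture, plus seeded
    random schema and instance generators for testing.
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
    igraph,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
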