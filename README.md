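# schemaforge

Class-based biomedical metadata schemas in R: author, extend, validate,
compare, and register JSON-LD schema documents with embedded JSON Schema
validation rules.

## The problem

Making biomedical research outputs FAIR (Findable, Accessible,
Interoperable, Reusable) starts with standardized metadata, and Schema.org
is the de-facto vocabulary for it. But Schema.org classes are usually both
too broad and too narrow for a given research use: a COVID-19 dataset needs
an `infectiousAgent` field that `schema:Dataset` does not have, and it needs
machine-checkable rules (is a property required? can it repeat? must its
values come from an ontology?) that Schema.org does not express. The usual
answer is a *profile*: a new class in its own namespace that subclasses an
existing one, inherits all of its properties, adds new ones, and embeds
validation rules.

schemaforge implements that workflow as an offline library for data
stewards, repository developers, and standardization communities:

- **schema model** — parse and canonically serialize JSON-LD documents in
  the RDF Schema dialect (`rdfs:Class` / `rdf:Property` nodes,
  `rdfs:subClassOf` links, `schema:domainIncludes` / `schema:rangeIncludes`
  property membership, an embedded `$validation` block per class);
- **hierarchy** — multi-parent class graphs, ancestor chains, and effective
  (inherited-inclusive) property sets with deterministic child-most,
  left-parent-first precedence;
- **authoring** — non-interactive class extension driven by request objects
  or YAML/JSON config files, and merging of per-class documents into one
  multi-class schema;
- **validation** — a restricted JSON Schema (draft-07 subset) engine with
  three marginality levels (required / recommended / optional), one/many
  cardinality encoded as `oneOf[R, array-of-R]`, ontology identifier
  constraints (e.g. `NCBITaxon:<digits>`), compiled rule inheritance,
  instance validation, and seeded example-markup generation;
- **registry** — a file-backed, searchable schema registry pre-seeded with
  a bundled Schema.org core snapshot; registration requires at least one
  class rooted in Schema.org (classless vocabularies are rejected);
- **compare** — shared/unique property partition across two to four
  classes;
- **fixtures** — a reconstruction of the 22-class COVID-19 Outbreak schema
  (six principal classes: Analysis, Dataset, ClinicalTrial,
  ComputationalTool, Protocol, Publication) plus seeded random schema and
  labeled instance generators.

## Worked example

Extend `schema:Dataset` into a COVID-19 dataset profile, constrain the new
`infectiousAgent` property to the NCBI Taxonomy, generate markup, validate
it, and compare the two classes:

```r
library(schemaforge)

core <- core_vocabulary()
req <- extension_request(
  base = "schema:Dataset", namespace = "covid", name = "Dataset",
  selected = c("name", "description"),
  new_properties = list(list(name = "infectiousAgent", range = "schema:Thing")),
  validation = list(name = list(type = "string"),
                    description = list(type = "string")),
  required = c("name", "infectiousAgent"), recommended = "description")
ext <- extend_class(list(core), req)
ext$classes[["covid:Dataset"]]$validation <- attach_ontology_constraint(
  ext$classes[["covid:Dataset"]]$validation, "infectiousAgent",
  list(prefix = "NCBITaxon", iri = "http://purl.obolibrary.org/obo/NCBITaxon_"))

docs <- list(core, ext)
g <- build_class_graph(docs)
compiled <- compile_validation(g, docs, "covid:Dataset")

example <- generate_example(compiled, seed = 42)
validate_document(example, compiled)
#> <validation_report> VALID: 0 violation(s), 1 warning(s)
#>   (warn) description: recommended property 'description' is absent

bad <- example
bad$infectiousAgent$identifier <- "SARS-CoV-2"
validate_document(bad, compiled)
#> <validation_report> INVALID: 1 violation(s), 1 warning(s)
#>   [pattern] infectiousAgent.identifier: 'SARS-CoV-2' does not match ^NCBITaxon:[0-9]+$|...

compare_classes(g, docs, c("schema:Dataset", "covid:Dataset"))
#> <comparison_result> schema:Dataset vs covid:Dataset
#>   shared (15): alternateName, author, citation, datePublished, description, ...
#>   unique to schema:Dataset (0):
#>   unique to covid:Dataset (1): infectiousAgent
```

The generated example is a JSON-LD instance: `"@context"`, `"@type":
"covid:Dataset"`, a `name` string, and an `infectiousAgent` object whose
`identifier` matches `NCBITaxon:<digits>`. The validation report's warning
reflects the *recommended* marginality level: absence is flagged but never
invalidates. The comparison shows the new class inheriting all fifteen
effective `schema:Dataset` properties and adding exactly one of its own.

A thin command-line wrapper over the same functions ships as
`inst/scripts/schemaforge` (`view`, `extend`, `validate`, `compare`,
`register`, `search`, `export`, `fixtures`; exit codes 0 = success, 1 =
invalid instance, 2 = usage/limit error).

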