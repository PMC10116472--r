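---
title: "Authoring and validating class-based metadata schemas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Authoring and validating class-based metadata schemas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schemaforge)
```

## The model

A *schema document* is one namespace's worth of metadata vocabulary: a set
of classes (conceptual entity types such as `Dataset`), a set of properties
(attributes with declared member classes and value types), and a JSON-LD
context binding prefixes like `schema` or `outbreak` to absolute IRI bases.
Documents follow RDF Schema conventions: classes are `rdfs:Class` nodes,
properties are `rdf:Property` nodes, parent links live under
`rdfs:subClassOf`, and property membership under `schema:domainIncludes`.
Because Schema.org organizes its vocabulary as a hierarchy rooted at
`Thing`, a new class derived from an existing one inherits every property
of its ancestors; profiles therefore only add what is missing and attach
validation rules to what matters for their community.

Validation is embedded per class under a `$validation` key as a restricted
JSON Schema block, and captures the three things plain Schema.org cannot
express:

* **marginality** — whether a property is required (absence invalidates),
  recommended (absence warns), or optional (absence is silent);
* **cardinality** — whether a property admits one value or many. `many`
  rewrites a rule `R` into `oneOf[R, array-of-R with minItems 1]`, so a
  scalar and a non-empty list both validate, and `one` restores the bare
  rule so arrays are rejected. No implicit coercion of scalars to
  singleton lists happens at validation time;
* **ontology constraints** — a property's values must be objects whose
  `identifier` matches an ontology's CURIE pattern
  (`NCBITaxon:<digits>`) or IRI form, the mechanism by which free-text
  fields are standardized against ontologies.

## Inheritance semantics

Classes may have several parents (Schema.org itself does). All inherited
computations use one deterministic precedence order: the class itself, then
its ancestors in preorder depth-first, left parent first, keeping the first
occurrence of each class. When two properties collide on a local name the
child-most definition wins, then the left parent's. The same order drives
compiled validation: the required set is the union along the lineage (a
child can only strengthen its ancestors' contracts, never weaken them),
and per-property rule conflicts resolve child-most wins. A total order had
to be fixed for reproducibility; union-with-child-override is the weakest
rule that keeps inheritance monotone, which the test suite asserts on
every random graph.

Parents that are named but not defined anywhere ("dangling") are allowed at
graph construction with a warning, so users can draft documents before
importing every dependency. They terminate ancestor chains and are
deliberately dead ends for `is_rooted_in_schemaorg()`: a class only counts
as rooted once the Schema.org ancestor it claims is actually loaded,
because rootedness gates registration.

## Canonical serialization

Round-trip stability is load-bearing: the registry stores documents as
files, comparisons and merge-deduplication rely on equality, and equality
is defined as byte-identical canonical serialization. The canonical form
fixes UTF-8, two-space indent, classes before properties in document
order, a fixed key order within nodes, and an alphabetically sorted
context. Two non-RDF keys extend the dialect: `x:principal` marks
top-level resource types (absent means false), and the top-level `@id`
carries the namespace's IRI base so the namespace survives a parse —
the dialect itself has no namespace slot, and recovering it from node
prefixes alone would be ambiguous for empty documents.

Empty descriptions are omitted on write and read back as empty strings, so
omission is stable under repeated round trips.

## The validation engine

The engine implements draft-07 semantics for a pinned keyword subset:
`type`, `enum`, `pattern`, `format`, `items`, `minItems`, `oneOf`, `anyOf`,
`$ref` (into a local `definitions` table), `description`, plus `properties`
and `required` for object-shaped values — the object keywords are needed by
the ontology constraint, which requires an object with a conforming
`identifier`. Anything outside the subset fails loudly at construction
time rather than being silently ignored: a rule that validates nothing is
worse than an error. Per draft-07, each keyword constrains only values of
its own JSON kind (`pattern` ignores non-strings, `minItems` non-arrays);
type mismatches are reported by `type` alone, keeping violation lists
small and attributable. `oneOf` demands exactly one matching branch. In
instance documents, `@context`, `@type` and `@id` are exempt from
unknown-property checks, and unknown non-`@` properties warn rather than
fail, matching Schema.org's permissive practice. Whether
recommended-but-absent properties should warn or stay silent was an open
call; warnings were chosen and isolated in the report type (`warnings`
never affect `valid`), so the choice is revisable without touching
verdicts.

Example generation inverts the engine: enums are sampled, anchored
patterns are synthesized by a small regex interpreter (literals, character
classes, `+`/`*`/`{n}` repetition, first branch of an alternation),
formats map to plausible dates/URIs, objects recurse over their required
members. Generation is deterministic per seed and restores the caller's
RNG state. Unsupported pattern constructs raise rather than guess, since a
generated example that fails its own rule set would poison the labeled
corpora built on top of it.

## Authoring and the registry

`extend_class()` emits a document that references its base by CURIE rather
than copying nodes: inheritance is reference semantics, so upstream
updates propagate, and the "selected" inherited properties appear only in
the new class's validation block (structurally they are already
inherited). Context merging refuses conflicting prefix bindings outright —
silently renaming a prefix would corrupt every identifier that uses it.
One namespace per document is assumed; multi-namespace composition goes
through `merge_schemas()`, which is idempotent on canonical form.

The registry is a directory of canonical `.jsonld` files plus one
versioned JSON index — deployment-grade databases are an operational
detail this library does not need. The bundled Schema.org snapshot is
pre-registered read-only under the namespace `schema`. The registration
gate (at least one class, at least one class rooted in Schema.org, fresh
namespace) is checked exhaustively over its eight combinations in the
acceptance tests. Re-registration semantics were unspecified territory; an
explicit `update = TRUE` overwrite is provided instead of guessing at
upsert behavior. Search ranks exact over prefix over substring matches,
alphabetical within ties, so CLI output is reproducible.

Comparison operates on property *local names* rather than full IRIs so
that an inherited `name` unifies across namespaces, as users expect when
comparing profiles; local names standing for different IRIs are surfaced
in a `name_collisions` footnote. Whether comparison should cover own-only
or inherited-inclusive sets was another open call: inherited-inclusive is
the default (that is what "what do these classes share" means in a
hierarchy) with `inherited = FALSE` exposed as a flag.

## The fixtures

`core_vocabulary()` is a deliberately miniature Schema.org: seventeen
classes, a single hierarchy rooted at `Thing`, and a curated five-to-
fifteen-property effective payload per class including the Thing-level
`name`, `description`, `identifier`, `url`. It is fixture scope, not a
fidelity claim — the real vocabulary has hundreds of classes and far
richer payloads. `MedicalTrial` and `MedicalObservationalStudy` are
included although the Outbreak schema uses neither, because the pair
(differing only in `trialDesign` vs `studyDesign`) illustrates exactly the
granularity problem profiles solve.

`build_outbreak_schema()` reconstructs the 22-class Outbreak schema with
its published class-to-parent mapping and six principal classes. Three
choices deserve a note. The source class printed for `ComputationalTool`
is "Software", which does not exist in Schema.org; `SoftwareApplication`
is used. `DataDownload` appears twice in the published table (once
standalone, once used by `Dataset`); it is materialized once,
non-principal, which keeps the principal count at six. Support-class usage
("used in" relationships) has no printed property names, so linking
properties are generated mechanically — lowerCamelCase of the support
class, domain = the using classes, range = the support class
(`outbreak:armGroup` on `ClinicalTrial` ranging over `outbreak:ArmGroup`).
The real schema's property inventory came from registry crosswalks that
are not reproduced here; property payloads beyond the published structure
are minimal.

## Random generators and what passing tests show

`random_schema()` grows acyclic multi-parent hierarchies by construction
(parents are earlier classes or `schema:Thing`) with random property
domains and typed validation rules. `sample_documents()` produces labeled
corpora: valid instances come straight from the generator, invalid ones
take exactly one named defect — a deleted required key, a wrong-typed
value, a scalar-cardinality value wrapped in an array, or an
ontology-constrained identifier replaced by free text. Each defect is
chosen to *guarantee* a violation, so labels are ground truth and any
validator/label disagreement is a bug, not tolerance: the acceptance suite
requires exact agreement on a 500-instance corpus and per-defect recall
of 1.

These generators emulate structural variety, not real-world messiness:
they do not produce deeply nested values, unicode edge cases, adversarial
patterns, multi-defect instances, or the scale of a production registry.
Passing tests therefore demonstrate correctness of the inheritance,
serialization, and validation semantics under the stated model — not
robustness against arbitrary JSON-LD found in the wild (full JSON-LD 1.1
processing, remote `$ref` resolution, and OWL reasoning are explicitly out
of scope).

## Problem sizes and numerical choices

The test suite uses 100 random documents for round-trip checks, 200 random
graphs (up to ~50 nodes with the core snapshot) against brute-force
ancestor/property oracles implemented independently (igraph path
enumeration and a naive preorder traversal), a 500-instance labeled
corpus, and exhaustive enumeration of the eight registration-gate
combinations — sizes chosen so the whole suite runs in about a minute and
a half while every code path and precedence rule is exercised many times
over. All randomness is seeded; reruns are bit-reproducible.

Known limitations: `one`-cardinality on an untyped (empty) rule cannot
reject arrays, since an empty rule accepts everything by JSON Schema
semantics — give the rule a `type` if arrays must be rejected. Pattern
synthesis covers anchored patterns of the kind the package itself emits;
exotic regexes raise at generation time. The registry performs no file
locking and assumes a single writer.
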