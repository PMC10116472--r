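# Canonical JSON-LD serialization. Dialect: top-level "@context", "@id"
# (the namespace's IRI base, so the namespace survives a round trip), then
# "@graph" holding class nodes ("@type": "rdfs:Class") followed by property
# nodes ("rdf:Property"), each with a fixed key order. Two-space indent,
# UTF-8, trailing newline — equal documents serialize byte-identically.

curie_ref_list <- function(ids) lapply(ids, function(id) list(`@id` = id))

class_node_json <- function(cls) {
  node <- list(`@id` = cls$id, `@type` = "rdfs:Class", `rdfs:label` = cls$label)
  if (nzchar(cls$description)) node$`rdfs:comment` <- cls$description
  if (length(cls$sub_class_of)) node$`rdfs:subClassOf` <- curie_ref_list(cls$sub_class_of)
  if (isTRUE(cls$principal)) node$`x:principal` <- TRUE
  if (!is.null(cls$validation)) node$`$validation` <- ruleset_to_json(cls$validation)
  node
}

property_node_json <- function(prop) {
  node <- list(`@id` = prop$id, `@type` = "rdf:Property", `rdfs:label` = prop$label)
  if (nzchar(prop$description)) node$`rdfs:comment` <- prop$description
  node$`schema:domainIncludes` <- curie_ref_list(prop$domain_includes)
  if (length(prop$range_includes)) {
    node$`schema:rangeIncludes` <- curie_ref_list(prop$range_includes)
  }
  node
}

document_json <- function(doc) {
  ctx <- doc$context[order(names(doc$context))]
  list(`@context` = as.list(stats::setNames(unname(ctx), names(ctx))),
       `@id` = unname(doc$context[[doc$namespace]]),
       `@graph` = c(lapply(unname(doc$classes), class_node_json),
                    lapply(unname(doc$properties), property_node_json)))
}

#' Serialize a schema document to canonical JSON-LD
#'
#' Produces a deterministic JSON-LD string: fixed key order, sorted context,
#' classes before properties in document order, two-space indentation.
#' Serializing equal documents yields byte-identical text, and
#' [parse_schema()] of the output reproduces the document.
#'
#' @param doc A [schema_document()].
#' @return A single JSON-LD string (with trailing newline).
#' @export
serialize_schema <- function(doc) {
  sf_assert(inherits(doc, "schema_document"), "document_error",
            "serialize_schema expects a schema_document")
  check_schema_document(doc)
  to_json_canonical(document_json(doc))
}

#' Write a schema document to a .json/.jsonld file
#'
#' @param doc A [schema_document()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_schema <- function(doc, path) {
  writeLines(serialize_schema(doc), path, sep = "")
  invisible(path)
}

# canonical-form equality used throughout (round-trip and merge checks)
canonical_equal <- function(a, b) identical(serialize_schema(a), serialize_schema(b))
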