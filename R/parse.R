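#' Parse a JSON-LD schema document
#'
#' Reads a JSON-LD string in the RDF Schema dialect used throughout this
#' package: an `@context` block binding prefixes, and an `@graph` node list
#' in which classes are typed `rdfs:Class` and properties `rdf:Property`.
#' Embedded `$validation` blocks are parsed into [validation_ruleset()]s.
#' Nodes with any other `@type` are reported in a warning, never silently
#' dropped. Every CURIE used must resolve against the context, or parsing
#' fails with a named error.
#'
#' @param text A JSON-LD document as a single string.
#' @param namespace Optional namespace override; by default it is recovered
#'   from the top-level `@id` (matched against the context) or, failing
#'   that, from the first class identifier's prefix.
#' @return A [schema_document()].
#' @export
parse_schema <- function(text, namespace = NULL) {
  sf_assert(is_scalar_string(text), "parse_error", "text must be a single string")
  raw <- tryCatch(jsonlite::fromJSON(text, simplifyVector = FALSE),
                  error = function(e) sf_error("parse_error",
                    paste0("malformed JSON: ", conditionMessage(e))))
  sf_assert(is.list(raw) && !is.null(raw$`@context`), "parse_error",
            "document has no @context block")
  ctx_raw <- raw$`@context`
  sf_assert(is.list(ctx_raw) && !is.null(names(ctx_raw)), "parse_error",
            "@context must be a prefix -> IRI map")
  context <- context_map(vapply(ctx_raw, as.character, ""))

  graph <- raw$`@graph` %||% list()
  classes <- list(); properties <- list(); unknown <- character()
  for (node in graph) {
    id <- node$`@id`
    sf_assert(is_scalar_string(id), "parse_error", "graph node without @id")
    types <- as.character(unlist(node$`@type`))
    if ("rdfs:Class" %in% types) {
      classes[[length(classes) + 1L]] <- parse_class_node(node)
    } else if ("rdf:Property" %in% types) {
      properties[[length(properties) + 1L]] <- parse_property_node(node)
    } else {
      unknown <- c(unknown, paste0(id, " (@type: ", paste(types, collapse = ", "), ")"))
    }
  }
  if (length(unknown)) {
    warning(paste0("skipped node(s) of unknown type: ", paste(unknown, collapse = "; ")),
            call. = FALSE)
  }

  if (is.null(namespace)) {
    top_id <- raw$`@id`
    if (is_scalar_string(top_id)) {
      hit <- names(context)[unname(context) == top_id]
      if (length(hit)) namespace <- hit[[1]]
    }
    if (is.null(namespace) && length(classes)) {
      namespace <- curie_prefix(classes[[1]]$id)
    }
    if (is.null(namespace) && length(properties)) {
      namespace <- curie_prefix(properties[[1]]$id)
    }
    sf_assert(!is.null(namespace), "parse_error",
              "cannot determine the document namespace (no @id, no nodes)")
  }
  schema_document(namespace, context, classes, properties)
}

parse_ref_ids <- function(x) {
  if (is.null(x)) return(character())
  if (is_scalar_string(x)) return(x)
  if (is.list(x) && !is.null(x$`@id`)) return(as.character(x$`@id`))
  vapply(x, function(e) {
    if (is_scalar_string(e)) e else as.character(e$`@id`)
  }, "")
}

parse_class_node <- function(node) {
  validation <- if (!is.null(node$`$validation`)) ruleset_from_json(node$`$validation`)
  class_definition(
    id = node$`@id`,
    sub_class_of = parse_ref_ids(node$`rdfs:subClassOf`),
    label = if (is.null(node$`rdfs:label`)) NULL else as.character(node$`rdfs:label`),
    description = as.character(node$`rdfs:comment` %||% ""),
    validation = validation,
    principal = isTRUE(node$`x:principal`))
}

parse_property_node <- function(node) {
  domain <- parse_ref_ids(node$`schema:domainIncludes`)
  sf_assert(length(domain) > 0L, "parse_error",
            paste0("property '", node$`@id`, "' has no schema:domainIncludes"))
  property_definition(
    id = node$`@id`,
    domain_includes = domain,
    range_includes = parse_ref_ids(node$`schema:rangeIncludes`),
    label = if (is.null(node$`rdfs:label`)) NULL else as.character(node$`rdfs:label`),
    description = as.character(node$`rdfs:comment` %||% ""))
}

#' Read a schema document from a .json/.jsonld file
#'
#' @param path Path to a JSON-LD schema file.
#' @inheritParams parse_schema
#' @return A [schema_document()].
#' @export
read_schema <- function(path, namespace = NULL) {
  sf_assert(file.exists(path), "io_error", paste0("no such file: ", path))
  parse_schema(paste(readLines(path, warn = FALSE), collapse = "\n"), namespace = namespace)
}
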