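#' Define a schema property
#'
#' A property is an RDFS-style attribute: it belongs to one or more classes
#' (`domain_includes`) and declares its expected value types
#' (`range_includes`), following the Schema.org `domainIncludes` /
#' `rangeIncludes` convention.
#'
#' @param id CURIE identifying the property, e.g. `"outbreak:infectiousAgent"`.
#' @param domain_includes Character vector of class CURIEs the property
#'   belongs to; must be non-empty.
#' @param range_includes Character vector of CURIEs naming expected value
#'   types (may be empty).
#' @param label Human-readable label; defaults to the CURIE's local name.
#' @param description Free-text description.
#' @return A `property_definition` object.
#' @export
property_definition <- function(id, domain_includes, range_includes = character(),
                                label = NULL, description = "") {
  sf_assert(is_scalar_string(id) && is_curie(id), "definition_error",
            "property id must be a CURIE string")
  domain_includes <- as.character(domain_includes)
  sf_assert(length(domain_includes) > 0L, "definition_error",
            paste0("property '", id, "' must name at least one domain class"))
  structure(
    list(id = id,
         label = if (is.null(label)) curie_local(id) else label,
         description = as.character(description),
         domain_includes = domain_includes,
         range_includes = as.character(range_includes)),
    class = "property_definition")
}

#' Define a schema class
#'
#' A class is a conceptual entity type (e.g. `Dataset`) described by a set of
#' properties. Classes may have several parents (`sub_class_of`), may embed a
#' [validation_ruleset()], and may be flagged as *principal* (a top-level
#' resource type rather than a support class referenced by others).
#'
#' @param id CURIE identifying the class, e.g. `"outbreak:Dataset"`.
#' @param sub_class_of Character vector of parent class CURIEs.
#' @param validation Optional [validation_ruleset()] embedded in the class.
#' @param principal Logical; `TRUE` marks a top-level resource type.
#' @inheritParams property_definition
#' @return A `class_definition` object.
#' @export
class_definition <- function(id, sub_class_of = character(), label = NULL,
                             description = "", validation = NULL,
                             principal = FALSE) {
  sf_assert(is_scalar_string(id) && is_curie(id), "definition_error",
            "class id must be a CURIE string")
  sub_class_of <- as.character(sub_class_of)
  sf_assert(!id %in% sub_class_of, "definition_error",
            paste0("class '", id, "' lists itself as a parent"))
  if (!is.null(validation)) {
    sf_assert(inherits(validation, "validation_ruleset"), "definition_error",
              "validation must be a validation_ruleset or NULL")
  }
  structure(
    list(id = id,
         label = if (is.null(label)) curie_local(id) else label,
         description = as.character(description),
         sub_class_of = sub_class_of,
         validation = validation,
         principal = isTRUE(principal)),
    class = "class_definition")
}

#' Assemble a schema document
#'
#' A schema document is one namespace's worth of class and property
#' definitions together with the JSON-LD context that makes its identifiers
#' resolvable. All invariants are checked on construction: the namespace must
#' be bound in the context, every CURIE used must resolve, and class/property
#' identifier sets must be disjoint.
#'
#' @param namespace Lowercase namespace token, e.g. `"outbreak"`; must appear
#'   as a prefix in `context`.
#' @param context A [context_map()] (or named character vector).
#' @param classes List of [class_definition()] objects (document order kept).
#' @param properties List of [property_definition()] objects.
#' @return A `schema_document` object.
#' @export
schema_document <- function(namespace, context, classes = list(), properties = list()) {
  if (!inherits(context, "context_map")) context <- context_map(context)
  doc <- structure(
    list(namespace = namespace, context = context,
         classes = classes, properties = properties),
    class = "schema_document")
  names(doc$classes) <- vapply(classes, `[[`, "", "id")
  names(doc$properties) <- vapply(properties, `[[`, "", "id")
  check_schema_document(doc)
  doc
}

check_schema_document <- function(doc) {
  sf_assert(is_scalar_string(doc$namespace) && nzchar(doc$namespace),
            "document_error", "namespace must be a non-empty string")
  sf_assert(doc$namespace %in% names(doc$context), "document_error",
            paste0("namespace '", doc$namespace, "' is not a prefix in the context"))
  cls_ids <- names(doc$classes) %||% character()
  prop_ids <- names(doc$properties) %||% character()
  sf_assert(!anyDuplicated(cls_ids), "document_error", "duplicate class id in document")
  sf_assert(!anyDuplicated(prop_ids), "document_error", "duplicate property id in document")
  overlap <- intersect(cls_ids, prop_ids)
  sf_assert(length(overlap) == 0L, "document_error",
            paste0("class and property id sets overlap: ", paste(overlap, collapse = ", ")))
  for (cls in doc$classes) {
    check_resolvable(doc$context, c(cls$id, cls$sub_class_of),
                     paste0("class '", cls$id, "'"))
    warn_case(cls$id, upper = TRUE)
  }
  for (prop in doc$properties) {
    check_resolvable(doc$context, c(prop$id, prop$domain_includes, prop$range_includes),
                     paste0("property '", prop$id, "'"))
    warn_case(prop$id, upper = FALSE)
  }
  invisible(doc)
}

# Schema.org convention: UpperCamelCase classes, lowerCamelCase properties.
# Violations warn, never error.
warn_case <- function(id, upper) {
  local <- curie_local(id)
  first <- substr(local, 1L, 1L)
  ok <- if (upper) first == toupper(first) else first == tolower(first)
  if (!ok) {
    warning(sprintf("identifier '%s' does not follow the %s convention", id,
                    if (upper) "UpperCamelCase class" else "lowerCamelCase property"),
            call. = FALSE)
  }
  invisible(NULL)
}

#' @export
print.schema_document <- function(x, ...) {
  cat(sprintf("<schema_document> namespace '%s'\n", x$namespace))
  cat(sprintf("  context: %s\n",
              paste(names(x$context), unname(x$context), sep = " -> ", collapse = "; ")))
  cat(sprintf("  classes: %d (%d principal), properties: %d\n",
              length(x$classes),
              sum(vapply(x$classes, function(c) isTRUE(c$principal), logical(1))),
              length(x$properties)))
  invisible(x)
}

#' @export
print.class_definition <- function(x, ...) {
  cat(sprintf("<class> %s%s", x$id, if (x$principal) " [principal]" else ""))
  if (length(x$sub_class_of)) cat(" <:", paste(x$sub_class_of, collapse = ", "))
  if (!is.null(x$validation)) cat(" (+validation)")
  cat("\n")
  invisible(x)
}

#' @export
print.property_definition <- function(x, ...) {
  cat(sprintf("<property> %s  domain: %s  range: %s\n", x$id,
              paste(x$domain_includes, collapse = ", "),
              paste(x$range_includes, collapse = ", ")))
  invisible(x)
}
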