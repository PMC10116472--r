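# Schema-editor logic: extend an existing class into a new namespace, and
# merge per-class documents into one multi-class schema. Both are pure
# functions; inputs are never mutated (R copy semantics) and extension
# references the base class by CURIE rather than copying its nodes.

merge_contexts <- function(contexts) {
  out <- character()
  for (ctx in contexts) {
    for (prefix in names(ctx)) {
      iri <- unname(ctx[[prefix]])
      if (prefix %in% names(out)) {
        sf_assert(identical(unname(out[[prefix]]), iri), "context_conflict",
                  paste0("prefix '", prefix, "' bound to two different IRIs: ",
                         out[[prefix]], " vs ", iri))
      } else {
        out[[prefix]] <- iri
      }
    }
  }
  context_map(out)
}

#' Describe a class extension
#'
#' An extension request captures everything the schema editor needs to
#' derive a new class from an existing one: the base class, the target
#' namespace and class name, which inherited properties should carry
#' validation ("selected"), brand-new properties, and the validation rules
#' and marginality for selected + new properties. Requests can also be read
#' from a YAML/JSON file with [read_extension_request()].
#'
#' @param base CURIE of the base class, e.g. `"schema:Dataset"`.
#' @param namespace Target namespace token, e.g. `"outbreak"`.
#' @param name Target class name (local, UpperCamelCase), e.g. `"Dataset"`.
#' @param prefix_iri IRI base bound to `namespace` in the new document's
#'   context; defaults to `https://example.org/<namespace>/`.
#' @param selected Local names of inherited properties to cover with
#'   validation; must exist in the base class's effective set.
#' @param new_properties List of new property specs; each a list with
#'   `name`, optional `label`, `description`, `range` (CURIE vector).
#' @param validation Named list of rule nodes for selected + new property
#'   names (names without an explicit rule get an empty, accept-anything
#'   rule).
#' @param required,recommended Marginality for selected + new names.
#' @param label,description Metadata for the new class.
#' @param principal Flag the new class as a principal (top-level) type.
#' @return An `extension_request` object.
#' @export
extension_request <- function(base, namespace, name,
                              prefix_iri = NULL,
                              selected = character(),
                              new_properties = list(),
                              validation = list(),
                              required = character(),
                              recommended = character(),
                              label = NULL, description = "",
                              principal = FALSE) {
  sf_assert(is_scalar_string(base) && is_curie(base), "request_error",
            "base must be a class CURIE")
  sf_assert(is_scalar_string(namespace) && grepl("^[a-z][a-z0-9]*$", namespace),
            "request_error", "namespace must be a lowercase token")
  sf_assert(is_scalar_string(name) && nzchar(name), "request_error",
            "target class name must be a non-empty string")
  structure(
    list(base = base, namespace = namespace, name = name,
         prefix_iri = prefix_iri %||% paste0("https://example.org/", namespace, "/"),
         selected = as.character(selected),
         new_properties = new_properties,
         validation = validation,
         required = as.character(required),
         recommended = as.character(recommended),
         label = label %||% name, description = description,
         principal = isTRUE(principal)),
    class = "extension_request")
}

#' @rdname extension_request
#' @param path Path to a `.yaml`/`.yml` or `.json` request file whose keys
#'   mirror the `extension_request()` arguments.
#' @export
read_extension_request <- function(path) {
  sf_assert(file.exists(path), "io_error", paste0("no such file: ", path))
  spec <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyVector = FALSE)
  }
  do.call(extension_request, spec[intersect(names(spec), names(formals(extension_request)))])
}

#' Extend an existing class into a new namespace
#'
#' Creates a new schema document containing one class that subclasses
#' `request$base`, any new properties (with the new class as their domain),
#' and a validation rule set covering exactly the selected inherited plus
#' new properties. All base properties remain inherited by reference:
#' nothing is copied, and the input documents are unchanged.
#'
#' @param docs List of [schema_document()]s that resolve the base class
#'   (typically the core vocabulary plus anything it extends).
#' @param request An [extension_request()].
#' @return A new [schema_document()] in the request's namespace.
#' @examples
#' core <- core_vocabulary()
#' req <- extension_request("schema:Dataset", "demo", "Dataset",
#'   new_properties = list(list(name = "infectiousAgent", range = "schema:Thing")),
#'   validation = list(infectiousAgent = list(type = "object")),
#'   required = "infectiousAgent")
#' ext <- extend_class(list(core), req)
#' @export
extend_class <- function(docs, request) {
  if (inherits(docs, "schema_document")) docs <- list(docs)
  sf_assert(inherits(request, "extension_request"), "request_error",
            "request must be an extension_request")
  graph <- suppressWarnings(build_class_graph(docs))
  check_in_graph(graph, request$base)
  sf_assert(is_rooted_in_schemaorg(graph, request$base), "request_error",
            paste0("base class '", request$base, "' is not rooted in Schema.org"))

  new_id <- paste0(request$namespace, ":", request$name)
  sf_assert(!new_id %in% graph$nodes, "request_collision",
            paste0("class '", new_id, "' already exists"))

  base_view <- effective_properties(graph, docs, request$base)
  missing_sel <- setdiff(request$selected, names(base_view$properties))
  sf_assert(length(missing_sel) == 0L, "request_error",
            paste0("selected propert(ies) not in the base's effective set: ",
                   paste(missing_sel, collapse = ", ")))

  new_names <- vapply(request$new_properties, function(p) as.character(p$name), "")
  clash <- intersect(new_names, request$selected)
  sf_assert(length(clash) == 0L, "request_error",
            paste0("new property name(s) collide with selected inherited ones: ",
                   paste(clash, collapse = ", ")))

  covered <- c(request$selected, new_names)
  stray_rules <- setdiff(names(request$validation), covered)
  sf_assert(length(stray_rules) == 0L, "request_error",
            paste0("validation rules for names outside selected+new: ",
                   paste(stray_rules, collapse = ", ")))
  rules <- stats::setNames(lapply(covered, function(nm) {
    request$validation[[nm]] %||% list()
  }), covered)
  ruleset <- if (length(covered)) {
    validation_ruleset(properties = rules, required = request$required,
                       recommended = request$recommended)
  }

  props <- lapply(request$new_properties, function(p) {
    property_definition(id = paste0(request$namespace, ":", p$name),
                        domain_includes = new_id,
                        range_includes = as.character(unlist(p$range %||% character())),
                        label = p$label %||% NULL,
                        description = as.character(p$description %||% ""))
  })

  ctx <- stats::setNames(request$prefix_iri, request$namespace)
  needed <- unique(c(curie_prefix(request$base),
                     curie_prefix(unlist(lapply(props, `[[`, "range_includes")))))
  needed <- setdiff(needed[!is_absolute_iri(needed)], request$namespace)
  pool <- merge_contexts(lapply(docs, `[[`, "context"))
  for (prefix in needed) {
    sf_assert(prefix %in% names(pool), "curie_unknown_prefix",
              paste0("prefix '", prefix, "' is not bound in any input document"))
    ctx[[prefix]] <- unname(pool[[prefix]])
  }

  cls <- class_definition(new_id, sub_class_of = request$base,
                          label = request$label, description = request$description,
                          validation = ruleset, principal = request$principal)
  schema_document(request$namespace, context_map(ctx), list(cls), props)
}

#' Merge several schema documents into one
#'
#' Combines per-class documents into a single multi-class schema: one merged
#' context (conflicting prefix bindings are refused, never renamed), every
#' distinct class and property exactly once, order preserved by input order.
#' Identical duplicate definitions are deduplicated; differing definitions
#' under the same id are an error. Merging is idempotent on canonical form.
#'
#' @param docs Non-empty list of [schema_document()]s.
#' @param namespace Namespace token for the merged document; must be bound
#'   in the merged context.
#' @return A single [schema_document()].
#' @export
merge_schemas <- function(docs, namespace) {
  if (inherits(docs, "schema_document")) docs <- list(docs)
  sf_assert(length(docs) >= 1L, "merge_error", "merge_schemas needs at least one document")
  context <- merge_contexts(lapply(docs, `[[`, "context"))
  sf_assert(namespace %in% names(context), "merge_error",
            paste0("namespace '", namespace, "' is not bound in the merged context"))
  classes <- list(); properties <- list()
  for (doc in docs) {
    for (cls in doc$classes) {
      if (cls$id %in% names(classes)) {
        sf_assert(identical(class_node_json(classes[[cls$id]]), class_node_json(cls)),
                  "merge_conflict",
                  paste0("class '", cls$id, "' has conflicting definitions"))
      } else {
        classes[[cls$id]] <- cls
      }
    }
    for (prop in doc$properties) {
      if (prop$id %in% names(properties)) {
        sf_assert(identical(property_node_json(properties[[prop$id]]),
                            property_node_json(prop)),
                  "merge_conflict",
                  paste0("property '", prop$id, "' has conflicting definitions"))
      } else {
        properties[[prop$id]] <- prop
      }
    }
  }
  schema_document(namespace, context, unname(classes), unname(properties))
}
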