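# File-backed schema registry: a directory of canonical .jsonld files plus
# one versioned JSON index. The Schema.org core snapshot is pre-registered
# read-only under namespace "schema". Registration is gated: a document must
# have at least one class, at least one class rooted in Schema.org, and a
# fresh namespace ("classless metadata vocabularies cannot be registered").

REGISTRY_INDEX_VERSION <- 1L

index_path <- function(store) file.path(store$dir, "index.json")
doc_path <- function(store, ns) file.path(store$dir, paste0(ns, ".jsonld"))

read_index <- function(store) {
  idx <- jsonlite::fromJSON(index_path(store), simplifyVector = FALSE)
  sf_assert(identical(as.integer(idx$version), REGISTRY_INDEX_VERSION),
            "registry_error", "unsupported registry index version")
  idx
}

write_index <- function(store, idx) {
  idx$records <- idx$records[order(names(idx$records))]
  idx$records <- as_json_map(idx$records)
  writeLines(to_json_canonical(idx), index_path(store), sep = "")
  invisible(idx)
}

record_json <- function(doc, source, readonly = FALSE, registered_at = NULL) {
  list(namespace = doc$namespace,
       registered_at = registered_at %||%
         format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
       source = source,
       readonly = readonly,
       classes = lapply(unname(doc$classes), function(c) {
         list(id = c$id, label = c$label)
       }))
}

#' Open (or create) a file-backed schema registry
#'
#' On first use the registry directory is created and the bundled
#' Schema.org core snapshot is pre-registered read-only under namespace
#' `"schema"`. Reopening an existing directory preserves every record
#' byte-identically.
#'
#' @param dir Registry directory path (created if needed).
#' @return A `schema_registry` handle.
#' @export
registry_open <- function(dir) {
  store <- structure(list(dir = dir), class = "schema_registry")
  if (!file.exists(index_path(store))) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    core <- core_vocabulary()
    write_schema(core, doc_path(store, "schema"))
    idx <- list(version = REGISTRY_INDEX_VERSION,
                records = stats::setNames(
                  list(record_json(core, "builtin:core_vocabulary", readonly = TRUE)),
                  "schema"))
    write_index(store, idx)
  } else {
    read_index(store)  # fail fast on version mismatch
  }
  store
}

registry_namespaces <- function(store) names(read_index(store)$records) %||% character()

registry_documents <- function(store) {
  lapply(stats::setNames(nm = registry_namespaces(store)), function(ns) {
    read_schema(doc_path(store, ns), namespace = ns)
  })
}

#' Register a schema document
#'
#' Persists a document in the registry after the registration gate:
#' documents with zero classes are rejected (classless vocabularies cannot
#' be registered), the document must graph-build together with the already
#' registered schemas, at least one class must be rooted in Schema.org, and
#' the namespace must not collide with an existing record (unless
#' `update = TRUE`; the built-in `"schema"` namespace is never updatable).
#' On rejection the store is unchanged.
#'
#' @param store A [registry_open()] handle.
#' @param doc A [schema_document()].
#' @param source Free-text provenance string stored in the record.
#' @param update Overwrite an existing record of the same namespace.
#' @return The stored record, invisibly.
#' @export
registry_register <- function(store, doc, source = "memory", update = FALSE) {
  sf_assert(inherits(doc, "schema_document"), "registry_error",
            "can only register a schema_document")
  sf_assert(length(doc$classes) > 0L, "registry_classless",
            paste0("namespace '", doc$namespace, "' has no classes; classless ",
                   "vocabularies cannot be registered"))
  idx <- read_index(store)
  existing <- names(idx$records)
  if (doc$namespace %in% existing) {
    sf_assert(update && !isTRUE(idx$records[[doc$namespace]]$readonly),
              "registry_collision",
              paste0("namespace '", doc$namespace, "' is already registered"))
  }
  others <- registry_documents(store)
  others[[doc$namespace]] <- NULL
  graph <- suppressWarnings(build_class_graph(c(unname(others), list(doc))))
  rooted <- vapply(names(doc$classes), function(id) {
    is_rooted_in_schemaorg(graph, id)
  }, logical(1))
  sf_assert(any(rooted), "registry_unrooted",
            paste0("namespace '", doc$namespace, "' has no class rooted in Schema.org"))
  write_schema(doc, doc_path(store, doc$namespace))
  rec <- record_json(doc, source)
  idx$records[[doc$namespace]] <- rec
  write_index(store, idx)
  invisible(rec)
}

#' Fetch a registered schema
#'
#' @inheritParams registry_register
#' @param namespace Registered namespace token.
#' @return A list with the index record fields plus `document`, the parsed
#'   [schema_document()].
#' @export
registry_get <- function(store, namespace) {
  idx <- read_index(store)
  sf_assert(namespace %in% names(idx$records), "registry_missing",
            paste0("no registered namespace '", namespace, "'"))
  rec <- idx$records[[namespace]]
  rec$document <- read_schema(doc_path(store, namespace), namespace = namespace)
  rec
}

#' Remove a registered schema
#'
#' @inheritParams registry_get
#' @return `TRUE` if a record was removed, `FALSE` if the namespace was
#'   absent. The read-only `"schema"` record cannot be removed.
#' @export
registry_deregister <- function(store, namespace) {
  idx <- read_index(store)
  if (!namespace %in% names(idx$records)) return(FALSE)
  sf_assert(!isTRUE(idx$records[[namespace]]$readonly), "registry_readonly",
            paste0("namespace '", namespace, "' is read-only"))
  idx$records[[namespace]] <- NULL
  write_index(store, idx)
  unlink(doc_path(store, namespace))
  TRUE
}

#' Search registered classes
#'
#' Case-insensitive substring search over class local names, labels, and
#' namespaces, with deterministic ranking: exact match beats prefix match
#' beats substring match, ties broken alphabetically by class id. An empty
#' query returns all classes (capped at `limit`).
#'
#' @inheritParams registry_register
#' @param query Query string.
#' @param limit Maximum number of rows returned.
#' @return A data frame with columns `namespace`, `class_id`, `label`,
#'   `match` (3 = exact, 2 = prefix, 1 = substring).
#' @export
registry_search <- function(store, query = "", limit = 100L) {
  idx <- read_index(store)
  rows <- list()
  q <- tolower(query)
  for (ns in names(idx$records)) {
    for (cls in idx$records[[ns]]$classes) {
      fields <- tolower(c(curie_local(cls$id), cls$label, ns))
      score <- if (!nzchar(q)) {
        1L
      } else {
        s <- 0L
        for (f in fields) {
          s <- max(s, if (f == q) 3L else if (startsWith(f, q)) 2L
                   else if (grepl(q, f, fixed = TRUE)) 1L else 0L)
        }
        s
      }
      if (score > 0L) {
        rows[[length(rows) + 1L]] <-
          data.frame(namespace = ns, class_id = cls$id, label = cls$label,
                     match = score, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(namespace = character(), class_id = character(),
                      label = character(), match = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$match, out$class_id), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, limit)
}

#' @export
print.schema_registry <- function(x, ...) {
  ns <- tryCatch(registry_namespaces(x), error = function(e) character())
  cat(sprintf("<schema_registry> %s (%d namespace(s): %s)\n", x$dir,
              length(ns), paste(ns, collapse = ", ")))
  invisible(x)
}
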