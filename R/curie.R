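#' Build a prefix-to-IRI context map
#'
#' A context map binds short prefixes (e.g. `"schema"`) to absolute IRI bases
#' (e.g. `"https://schema.org/"`), mirroring a JSON-LD `@context` block.
#' Compact identifiers (CURIEs) of the form `prefix:local` are expanded against
#' it with [resolve_curie()].
#'
#' @param ... Named arguments, one per prefix: `schema = "https://schema.org/"`.
#'   A single named character vector may be supplied instead.
#' @return A named character vector of class `context_map`.
#' @examples
#' ctx <- context_map(schema = "https://schema.org/")
#' resolve_curie(ctx, "schema:Dataset")
#' @export
context_map <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && is.character(args[[1]])) {
    x <- args[[1]]
  } else {
    x <- unlist(args)
  }
  x <- stats::setNames(as.character(x), names(x))
  validate_context(x)
  structure(x, class = "context_map")
}

validate_context <- function(x) {
  nms <- names(x)
  sf_assert(length(x) == 0L || (!is.null(nms) && all(nzchar(nms))),
            "context_error", "every context entry must be named by a prefix")
  sf_assert(!any(grepl(":", nms, fixed = TRUE)),
            "context_error", "context prefixes must not contain ':'")
  sf_assert(!anyDuplicated(nms),
            "context_error", "duplicate prefix in context")
  bad <- x[!is_absolute_iri(x)]
  sf_assert(length(bad) == 0L, "context_error",
            paste0("context IRI bases must be absolute: ", paste(bad, collapse = ", ")))
  invisible(x)
}

#' @rdname resolve_curie
#' @export
is_absolute_iri <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*://", x)
}

is_curie <- function(x) {
  !is_absolute_iri(x) & grepl("^[^:]+:.+$", x)
}

curie_prefix <- function(x) sub(":.*$", "", x)

curie_local <- function(x) sub("^[^:]+:", "", x)

#' Expand a compact identifier against a context
#'
#' Absolute IRIs pass through unchanged; a CURIE `prefix:local` expands to the
#' prefix's IRI base followed by the local name.
#'
#' @param context A [context_map()].
#' @param token An absolute IRI or a CURIE string.
#' @return The absolute IRI as a string.
#' @export
resolve_curie <- function(context, token) {
  sf_assert(is_scalar_string(token) && nzchar(token), "curie_error",
            "token must be a non-empty string")
  if (is_absolute_iri(token)) return(token)
  sf_assert(grepl(":", token, fixed = TRUE), "curie_error",
            paste0("not an absolute IRI and not a CURIE: '", token, "'"))
  prefix <- curie_prefix(token)
  local <- curie_local(token)
  sf_assert(nzchar(local), "curie_error",
            paste0("CURIE with empty local name: '", token, "'"))
  sf_assert(prefix %in% names(context), "curie_unknown_prefix",
            paste0("unknown prefix '", prefix, "' in '", token, "'"))
  paste0(unname(context[[prefix]]), local)
}

# every CURIE used in a document must resolve; absolute IRIs are fine
check_resolvable <- function(context, tokens, where) {
  for (tok in tokens) {
    if (is_absolute_iri(tok)) next
    prefix <- curie_prefix(tok)
    sf_assert(grepl(":", tok, fixed = TRUE) && nzchar(curie_local(tok)),
              "curie_error", paste0("malformed identifier '", tok, "' in ", where))
    sf_assert(prefix %in% names(context), "curie_unknown_prefix",
              paste0("unresolvable prefix '", prefix, "' (", tok, ") in ", where))
  }
  invisible(TRUE)
}
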