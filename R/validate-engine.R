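# Instance validation against a compiled rule set. JSON values are the R
# shapes jsonlite::fromJSON(simplifyVector = FALSE) produces: named lists are
# objects, unnamed lists are arrays, length-one atomics are scalars.

json_is_object <- function(x) {
  is.list(x) && (length(x) == 0L || (!is.null(names(x)) && all(nzchar(names(x)))))
}

json_is_array <- function(x) {
  (is.list(x) && (length(x) == 0L || is.null(names(x)))) ||
    (is.atomic(x) && !is.null(x) && length(x) > 1L)
}

json_elements <- function(x) if (is.list(x)) x else as.list(x)

matches_type <- function(value, type) {
  switch(type,
    string = is.character(value) && length(value) == 1L,
    number = is.numeric(value) && length(value) == 1L,
    integer = is.numeric(value) && length(value) == 1L && value == trunc(value),
    boolean = is.logical(value) && length(value) == 1L,
    null = is.null(value),
    object = json_is_object(value),
    array = json_is_array(value),
    FALSE)
}

violation <- function(path, keyword, message) {
  list(path = path, keyword = keyword, message = message)
}

# draft-07 semantics for the supported subset: each keyword constrains only
# values of its own kind (pattern ignores non-strings, items non-arrays, ...)
validate_value <- function(value, rule, defs, path) {
  v <- list()
  if (!is.null(rule$`$ref`)) {
    target <- sub("^#/definitions/", "", rule$`$ref`)
    sf_assert(target %in% names(defs), "ruleset_error",
              paste0("$ref to missing definition '", target, "'"))
    v <- c(v, validate_value(value, defs[[target]], defs, path))
  }
  if (!is.null(rule$type)) {
    types <- as.character(unlist(rule$type))
    if (!any(vapply(types, matches_type, logical(1), value = value))) {
      v[[length(v) + 1L]] <- violation(path, "type",
        paste0("expected ", paste(types, collapse = " or ")))
    }
  }
  if (!is.null(rule$enum)) {
    hit <- any(vapply(rule$enum, function(e) identical(unlist(e), unlist(value)), logical(1)))
    if (!hit) v[[length(v) + 1L]] <- violation(path, "enum", "value not in enumeration")
  }
  if (!is.null(rule$pattern) && is.character(value) && length(value) == 1L) {
    if (!grepl(rule$pattern, value, perl = TRUE)) {
      v[[length(v) + 1L]] <- violation(path, "pattern",
        paste0("'", value, "' does not match ", rule$pattern))
    }
  }
  if (!is.null(rule$format) && is.character(value) && length(value) == 1L) {
    ok <- switch(rule$format,
      date = grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}$", value),
      `date-time` = grepl("^[0-9]{4}-[0-9]{2}-[0-9]{2}T[0-9:.]+(Z|[+-][0-9:]+)?$", value),
      uri = is_absolute_iri(value),
      email = grepl("^[^@[:space:]]+@[^@[:space:]]+$", value),
      TRUE)  # unknown formats are annotations, per draft-07
    if (!ok) v[[length(v) + 1L]] <- violation(path, "format",
      paste0("'", value, "' is not a valid ", rule$format))
  }
  if (json_is_array(value)) {
    elems <- json_elements(value)
    if (!is.null(rule$minItems) && length(elems) < rule$minItems) {
      v[[length(v) + 1L]] <- violation(path, "minItems",
        paste0("fewer than ", rule$minItems, " item(s)"))
    }
    if (!is.null(rule$items)) {
      for (i in seq_along(elems)) {
        v <- c(v, validate_value(elems[[i]], rule$items, defs, paste0(path, "[", i, "]")))
      }
    }
  }
  if (json_is_object(value)) {
    for (req in unlist(rule$required)) {
      if (!req %in% names(value)) {
        v[[length(v) + 1L]] <- violation(paste0(path, ".", req), "required",
                                         paste0("missing required member '", req, "'"))
      }
    }
    for (nm in names(rule$properties)) {
      if (nm %in% names(value)) {
        v <- c(v, validate_value(value[[nm]], rule$properties[[nm]], defs,
                                 paste0(path, ".", nm)))
      }
    }
  }
  if (!is.null(rule$oneOf)) {
    hits <- sum(vapply(rule$oneOf, function(branch) {
      length(validate_value(value, branch, defs, path)) == 0L
    }, logical(1)))
    if (hits != 1L) {
      v[[length(v) + 1L]] <- violation(path, "oneOf",
        paste0(hits, " of ", length(rule$oneOf), " alternatives matched (need exactly 1)"))
    }
  }
  if (!is.null(rule$anyOf)) {
    hit <- any(vapply(rule$anyOf, function(branch) {
      length(validate_value(value, branch, defs, path)) == 0L
    }, logical(1)))
    if (!hit) v[[length(v) + 1L]] <- violation(path, "anyOf", "no alternative matched")
  }
  v
}

#' Validate an instance document against compiled rules
#'
#' Checks a JSON metadata instance (a named list with an `"@type"` member)
#' against a [compile_validation()] result. Missing required properties and
#' rule breaches are violations; missing recommended properties and unknown
#' non-`@` properties are warnings only and never affect validity. A
#' mismatched `"@type"` is a violation, not an exception. `"@context"`,
#' `"@type"` and `"@id"` are exempt from unknown-property checks.
#'
#' @param instance A named list (parsed JSON object) with an `"@type"`.
#' @param compiled A `validation_ruleset`, typically from
#'   [compile_validation()].
#' @return A `validation_report` with fields `valid` (logical), `violations`
#'   (list of path/keyword/message records) and `warnings`.
#' @export
validate_document <- function(instance, compiled) {
  sf_assert(inherits(compiled, "validation_ruleset"), "ruleset_error",
            "compiled must be a validation_ruleset")
  sf_assert(json_is_object(instance) && length(instance) > 0L, "instance_error",
            "instance must be a non-empty JSON object (named list)")
  violations <- list(); warnings <- list()
  expected <- attr(compiled, "class_id")
  itype <- instance[["@type"]]
  if (!is_scalar_string(itype)) {
    violations[[length(violations) + 1L]] <-
      violation("@type", "required", "instance has no @type")
  } else if (!is.null(expected) && !itype %in% c(expected, curie_local(expected))) {
    violations[[length(violations) + 1L]] <-
      violation("@type", "type", paste0("@type '", itype, "' does not name '", expected, "'"))
  }
  for (nm in compiled$required) {
    if (!nm %in% names(instance)) {
      violations[[length(violations) + 1L]] <-
        violation(nm, "required", paste0("missing required property '", nm, "'"))
    }
  }
  for (nm in compiled$recommended) {
    if (!nm %in% names(instance)) {
      warnings[[length(warnings) + 1L]] <-
        list(path = nm, message = paste0("recommended property '", nm, "' is absent"))
    }
  }
  for (nm in names(instance)) {
    if (startsWith(nm, "@")) next
    if (nm %in% names(compiled$properties)) {
      violations <- c(violations,
                      validate_value(instance[[nm]], compiled$properties[[nm]],
                                     compiled$definitions, nm))
    } else {
      warnings[[length(warnings) + 1L]] <-
        list(path = nm, message = paste0("unknown property '", nm, "' (no rule)"))
    }
  }
  structure(list(valid = length(violations) == 0L,
                 violations = violations, warnings = warnings),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("<validation_report> %s: %d violation(s), %d warning(s)\n",
              if (x$valid) "VALID" else "INVALID",
              length(x$violations), length(x$warnings)))
  for (v in x$violations) cat(sprintf("  [%s] %s: %s\n", v$keyword, v$path, v$message))
  for (w in x$warnings) cat(sprintf("  (warn) %s: %s\n", w$path, w$message))
  invisible(x)
}

render_report <- function(report, format = "text") {
  if (format == "json") {
    return(to_json_canonical(list(
      valid = report$valid,
      violations = lapply(report$violations, identity),
      warnings = lapply(report$warnings, identity))))
  }
  paste0(paste(utils::capture.output(print(report)), collapse = "\n"), "\n")
}
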