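# Embedded validation rules: a restricted JSON Schema (draft-07 semantics)
# subset carried on class definitions. Supported keywords only; anything else
# fails loudly at construction/compile time rather than being ignored.

RULE_KEYWORDS <- c("type", "format", "enum", "pattern", "minItems", "items",
                   "properties", "required", "oneOf", "anyOf", "$ref",
                   "description")

JSON_TYPES <- c("string", "number", "integer", "boolean", "object", "array", "null")

#' Build an embedded validation rule set
#'
#' A rule set attaches JSON Schema value rules to a class's properties and
#' records their *marginality*: `required` properties must be present for an
#' instance to be valid, `recommended` properties produce a warning when
#' absent, and everything else is optional. Rules are restricted to a
#' draft-07 keyword subset (`type`, `enum`, `pattern`, `format`, `items`,
#' `minItems`, `oneOf`, `anyOf`, `$ref`, `properties`, `required`,
#' `description`); unsupported keywords are rejected.
#'
#' @param properties Named list mapping property local names to rule nodes
#'   (plain R lists mirroring JSON Schema objects).
#' @param required,recommended Character vectors of property local names;
#'   must be disjoint and every name must have a rule in `properties`.
#' @param definitions Named list of reusable rule nodes addressable via
#'   `"$ref": "#/definitions/<name>"`.
#' @return A `validation_ruleset` object.
#' @examples
#' rs <- validation_ruleset(
#'   properties = list(name = list(type = "string")),
#'   required = "name")
#' @export
validation_ruleset <- function(properties = list(), required = character(),
                               recommended = character(), definitions = list()) {
  required <- as.character(required)
  recommended <- as.character(recommended)
  sf_assert(length(properties) == 0L || !is.null(names(properties)),
            "ruleset_error", "properties must be a named list of rules")
  sf_assert(length(intersect(required, recommended)) == 0L, "ruleset_error",
            "required and recommended sets must be disjoint")
  missing_rule <- setdiff(c(required, recommended), names(properties))
  sf_assert(length(missing_rule) == 0L, "ruleset_error",
            paste0("marginality set names properties without a rule: ",
                   paste(missing_rule, collapse = ", ")))
  properties <- lapply(properties, canonical_rule)
  definitions <- lapply(definitions, canonical_rule)
  for (nm in names(properties)) {
    meta_validate_rule(properties[[nm]], names(definitions), paste0("rule '", nm, "'"))
  }
  for (nm in names(definitions)) {
    meta_validate_rule(definitions[[nm]], names(definitions), paste0("definition '", nm, "'"))
  }
  structure(list(properties = properties, required = required,
                 recommended = recommended, definitions = definitions),
            class = "validation_ruleset")
}

# normalize an R-authored or JSON-parsed rule into one canonical shape:
# fixed key order, list-typed arrays, integer minItems
canonical_rule <- function(rule) {
  sf_assert(is.list(rule), "ruleset_error", "a rule must be a list (JSON object)")
  if (length(rule) == 0L) return(structure(list(), names = character(0)))
  sf_assert(!is.null(names(rule)) && all(nzchar(names(rule))),
            "ruleset_error", "rule keys must be named")
  out <- list()
  for (key in RULE_KEYWORDS) {
    if (!key %in% names(rule)) next
    val <- rule[[key]]
    out[[key]] <- switch(key,
      type = if (length(val) > 1L) as.list(as.character(unlist(val))) else as.character(unlist(val)),
      enum = as.list(unlist(val, recursive = FALSE)),
      required = as.list(as.character(unlist(val))),
      minItems = as.integer(val),
      items = canonical_rule(val),
      properties = lapply(val, canonical_rule),
      oneOf = lapply(unname(val), canonical_rule),
      anyOf = lapply(unname(val), canonical_rule),
      val)
  }
  unknown <- setdiff(names(rule), RULE_KEYWORDS)
  for (key in unknown) out[[key]] <- rule[[key]]  # kept so meta-validation can name it
  out
}

meta_validate_rule <- function(rule, def_names, where) {
  unknown <- setdiff(names(rule), RULE_KEYWORDS)
  sf_assert(length(unknown) == 0L, "unsupported_keyword",
            paste0(where, " uses unsupported keyword(s): ", paste(unknown, collapse = ", ")))
  if (!is.null(rule$type)) {
    bad <- setdiff(unlist(rule$type), JSON_TYPES)
    sf_assert(length(bad) == 0L, "ruleset_error",
              paste0(where, " has unknown type(s): ", paste(bad, collapse = ", ")))
  }
  if (!is.null(rule$enum)) {
    sf_assert(length(rule$enum) > 0L, "ruleset_error", paste0(where, " has an empty enum"))
  }
  if (!is.null(rule$pattern)) {
    sf_assert(is_scalar_string(rule$pattern), "ruleset_error",
              paste0(where, " pattern must be a string"))
  }
  if (!is.null(rule$`$ref`)) {
    sf_assert(is_scalar_string(rule$`$ref`) && grepl("^#/definitions/", rule$`$ref`),
              "ruleset_error", paste0(where, " $ref must look like '#/definitions/<name>'"))
    target <- sub("^#/definitions/", "", rule$`$ref`)
    sf_assert(target %in% def_names, "ruleset_error",
              paste0(where, " $ref targets missing definition '", target, "'"))
  }
  if (!is.null(rule$items)) meta_validate_rule(rule$items, def_names, paste0(where, "/items"))
  for (branch in rule$oneOf) meta_validate_rule(branch, def_names, paste0(where, "/oneOf"))
  for (branch in rule$anyOf) meta_validate_rule(branch, def_names, paste0(where, "/anyOf"))
  for (nm in names(rule$properties)) {
    meta_validate_rule(rule$properties[[nm]], def_names, paste0(where, "/properties/", nm))
  }
  invisible(TRUE)
}

ruleset_has <- function(ruleset, name) {
  sf_assert(inherits(ruleset, "validation_ruleset"), "ruleset_error",
            "expected a validation_ruleset")
  sf_assert(name %in% names(ruleset$properties), "ruleset_unknown_property",
            paste0("no rule for property '", name, "'"))
  invisible(TRUE)
}

#' Set the marginality of a property
#'
#' Marginality records whether a property is `required` (absence is a
#' violation), `recommended` (absence is a warning), or `optional` (absence
#' is silent). Toggling marginality never changes the property's value rule.
#'
#' @param ruleset A [validation_ruleset()].
#' @param name Property local name; must have a rule.
#' @param level One of `"required"`, `"recommended"`, `"optional"`.
#' @return The updated rule set.
#' @export
set_marginality <- function(ruleset, name, level = c("required", "recommended", "optional")) {
  level <- match.arg(level)
  ruleset_has(ruleset, name)
  ruleset$required <- setdiff(ruleset$required, name)
  ruleset$recommended <- setdiff(ruleset$recommended, name)
  if (level == "required") ruleset$required <- c(ruleset$required, name)
  if (level == "recommended") ruleset$recommended <- c(ruleset$recommended, name)
  ruleset
}

# a "many" rule is exactly oneOf[scalar, non-empty array of scalar]
is_many_rule <- function(rule) {
  identical(names(rule), "oneOf") && length(rule$oneOf) == 2L &&
    identical(rule$oneOf[[2]],
              canonical_rule(list(type = "array", minItems = 1L, items = rule$oneOf[[1]])))
}

#' Set the cardinality of a property
#'
#' Cardinality records whether a property admits one value or many. `many`
#' rewrites the rule `R` to `oneOf[R, array-of-R with minItems 1]`, so both a
#' single value and a non-empty list validate; `one` restores the bare rule
#' (arrays are then rejected by the rule's own type). Applying `many` twice
#' is idempotent, never nested, and toggling cardinality never changes the
#' required/recommended sets.
#'
#' @inheritParams set_marginality
#' @param arity `"one"` or `"many"`.
#' @return The updated rule set.
#' @export
set_cardinality <- function(ruleset, name, arity = c("one", "many")) {
  arity <- match.arg(arity)
  ruleset_has(ruleset, name)
  rule <- ruleset$properties[[name]]
  if (arity == "many") {
    if (!is_many_rule(rule)) {
      ruleset$properties[[name]] <- canonical_rule(
        list(oneOf = list(rule, list(type = "array", minItems = 1L, items = rule))))
    }
  } else {
    if (is_many_rule(rule)) ruleset$properties[[name]] <- rule$oneOf[[1]]
  }
  ruleset
}

escape_regex <- function(x) gsub("([.\\\\+*?^$(){}=!<>|:#/\\[\\]-])", "\\\\\\1", x, perl = TRUE)

ontology_identifier_rule <- function(prefix, iri = NULL, description = NULL) {
  pats <- paste0("^", prefix, ":[0-9]+$")
  if (!is.null(iri) && nzchar(iri)) {
    pats <- c(pats, paste0("^", escape_regex(iri), "[0-9]+$"))
  }
  canonical_rule(list(
    type = "object",
    properties = list(identifier = list(type = "string",
                                        pattern = paste(pats, collapse = "|"))),
    required = list("identifier"),
    description = description %||%
      paste0("A term from the ", prefix, " ontology, given as an object whose ",
             "'identifier' is a ", prefix, " CURIE or IRI.")))
}

#' Constrain a property's values to an ontology
#'
#' Rewrites the property's rule so that values must be objects carrying an
#' `identifier` that matches the ontology's CURIE pattern
#' (`"<prefix>:<digits>"`) or, when an IRI base is given, the corresponding
#' full IRI. This is how, for example, an `infectiousAgent` property is
#' standardized against the NCBI Taxonomy (`NCBITaxon:<digits>`). If the rule
#' currently allows many values, the constraint is applied to the scalar
#' branch and the many-shape is preserved.
#'
#' @inheritParams set_marginality
#' @param ontology List with elements `prefix` (CURIE prefix, required) and
#'   optionally `iri` (absolute IRI base for expanded identifiers).
#' @return The updated rule set.
#' @examples
#' rs <- validation_ruleset(properties = list(infectiousAgent = list()))
#' rs <- attach_ontology_constraint(rs, "infectiousAgent",
#'   list(prefix = "NCBITaxon", iri = "http://purl.obolibrary.org/obo/NCBITaxon_"))
#' @export
attach_ontology_constraint <- function(ruleset, name, ontology) {
  ruleset_has(ruleset, name)
  sf_assert(is.list(ontology) && is_scalar_string(ontology$prefix) && nzchar(ontology$prefix),
            "ruleset_error", "ontology spec must carry a non-empty 'prefix'")
  new_rule <- ontology_identifier_rule(ontology$prefix, ontology$iri)
  old <- ruleset$properties[[name]]
  if (is_many_rule(old)) {
    ruleset$properties[[name]] <- canonical_rule(
      list(oneOf = list(new_rule, list(type = "array", minItems = 1L, items = new_rule))))
  } else {
    ruleset$properties[[name]] <- new_rule
  }
  ruleset
}

# ---- JSON round-trip for embedded rulesets --------------------------------

ruleset_to_json <- function(rs) {
  out <- list()
  if (length(rs$properties)) out$properties <- lapply(rs$properties, identity)
  if (length(rs$required)) out$required <- as.list(rs$required)
  if (length(rs$recommended)) out$recommended <- as.list(rs$recommended)
  if (length(rs$definitions)) out$definitions <- rs$definitions
  as_json_map(out)
}

ruleset_from_json <- function(x) {
  validation_ruleset(
    properties = x$properties %||% list(),
    required = as.character(unlist(x$required)),
    recommended = as.character(unlist(x$recommended)),
    definitions = x$definitions %||% list())
}

#' Compile the effective validation rules of a class
#'
#' Walks the class and its ancestors (child-most first, left parent first)
#' and merges their embedded rule sets: the required set is the union of all
#' ancestors' required sets, recommended names not promoted to required are
#' unioned likewise, and when two classes rule the same property the
#' child-most rule wins. Every ruled name must belong to the class's
#' effective property set. The result carries the owning class id and the
#' merged context as attributes so it can validate and generate instances on
#' its own.
#'
#' @param graph A [build_class_graph()] result covering `docs`.
#' @param docs List of [schema_document()]s.
#' @param class_id CURIE of the class to compile.
#' @return A `validation_ruleset` with attributes `class_id` and `context`.
#' @export
compile_validation <- function(graph, docs, class_id) {
  view <- effective_properties(graph, docs, class_id)
  lineage <- c(class_id, view$ancestors)
  class_index <- do.call(c, lapply(docs, `[[`, "classes"))
  props <- list(); required <- character(); recommended <- character(); defs <- list()
  for (cid in lineage) {
    cls <- class_index[[cid]]
    if (is.null(cls) || is.null(cls$validation)) next
    rs <- cls$validation
    for (nm in names(rs$properties)) {
      if (!nm %in% names(props)) props[[nm]] <- rs$properties[[nm]]
    }
    required <- union(required, rs$required)
    recommended <- union(recommended, rs$recommended)
    for (nm in names(rs$definitions)) {
      if (!nm %in% names(defs)) defs[[nm]] <- rs$definitions[[nm]]
    }
  }
  outside <- setdiff(names(props), names(view$properties))
  sf_assert(length(outside) == 0L, "ruleset_error",
            paste0("validation rules for '", class_id,
                   "' reference properties outside its effective set: ",
                   paste(outside, collapse = ", ")))
  compiled <- validation_ruleset(properties = props, required = required,
                                 recommended = setdiff(recommended, required),
                                 definitions = defs)
  attr(compiled, "class_id") <- class_id
  attr(compiled, "context") <- merge_contexts(lapply(docs, `[[`, "context"))
  compiled
}

#' Export a compiled rule set as a standalone JSON Schema
#'
#' Writes a draft-07 JSON Schema document usable by third-party validators.
#' The non-standard `recommended` key is carried through (third-party
#' validators ignore unknown keywords).
#'
#' @param compiled A [compile_validation()] result (or any rule set).
#' @param path Optional file path; when given the schema is written there.
#' @return The JSON text, invisibly when `path` is given.
#' @export
export_json_schema <- function(compiled, path = NULL) {
  body <- list(`$schema` = "http://json-schema.org/draft-07/schema#",
               type = "object")
  cid <- attr(compiled, "class_id")
  if (!is.null(cid)) body$title <- cid
  body$properties <- as_json_map(compiled$properties)
  if (length(compiled$required)) body$required <- as.list(compiled$required)
  if (length(compiled$recommended)) body$recommended <- as.list(compiled$recommended)
  if (length(compiled$definitions)) body$definitions <- compiled$definitions
  txt <- to_json_canonical(body)
  if (!is.null(path)) {
    writeLines(txt, path, sep = "")
    return(invisible(txt))
  }
  txt
}

#' @export
print.validation_ruleset <- function(x, ...) {
  cat(sprintf("<validation_ruleset> %d rule(s); required: {%s}; recommended: {%s}\n",
              length(x$properties),
              paste(x$required, collapse = ", "),
              paste(x$recommended, collapse = ", ")))
  invisible(x)
}
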