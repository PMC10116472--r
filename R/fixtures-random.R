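# Seeded random generators: schema documents for property-style tests and
# labeled valid/invalid instance corpora with one named injected defect per
# invalid instance. Deterministic per seed.

#' Generate a random schema document
#'
#' Produces a deterministic random schema for a given seed: classes form an
#' acyclic multi-parent hierarchy (parents are earlier classes or
#' `schema:Thing`, so the result always graph-builds against the core
#' vocabulary), and properties are assigned random domains among the
#' generated classes. A few classes receive validation rules over their own
#' properties.
#'
#' @param seed Integer seed.
#' @param n_classes,n_props Number of classes and properties (`n_classes >= 1`).
#' @param namespace Namespace token; defaults to `"rnd"`.
#' @param p_multiparent Probability that a class gets a second parent.
#' @param p_validation Probability that a class with own properties gets a
#'   validation rule set.
#' @return A [schema_document()].
#' @export
random_schema <- function(seed, n_classes = 6L, n_props = 10L,
                          namespace = "rnd", p_multiparent = 0.3,
                          p_validation = 0.5) {
  sf_assert(n_classes >= 1L, "generate_error", "n_classes must be >= 1")
  with_seed(seed, {
    ctx <- context_map(stats::setNames(
      c(paste0("https://example.org/", namespace, "/"), SCHEMA_ORG_IRI),
      c(namespace, "schema")))
    cls_names <- paste0("Class", seq_len(n_classes))
    cls_ids <- paste0(namespace, ":", cls_names)
    classes <- vector("list", n_classes)
    for (i in seq_len(n_classes)) {
      pool <- c("schema:Thing", if (i > 1L) cls_ids[seq_len(i - 1L)])
      parents <- sample(pool, 1L)
      if (length(pool) > 1L && stats::runif(1) < p_multiparent) {
        parents <- c(parents, sample(setdiff(pool, parents), 1L))
      }
      classes[[i]] <- class_definition(cls_ids[i], sub_class_of = parents,
                                       description = paste0("Random class ", i, "."))
    }
    properties <- lapply(seq_len(n_props), function(j) {
      k <- if (stats::runif(1) < 0.2 && n_classes > 1L) 2L else 1L
      property_definition(paste0(namespace, ":prop", j),
                          domain_includes = sample(cls_ids, k),
                          range_includes = "schema:Text")
    })
    prop_types <- c("string", "integer", "number", "boolean")
    for (i in seq_len(n_classes)) {
      own <- Filter(function(p) cls_ids[i] %in% p$domain_includes, properties)
      if (length(own) == 0L || stats::runif(1) >= p_validation) next
      take <- sample(own, sample.int(length(own), 1L))
      rules <- stats::setNames(lapply(take, function(p) {
        list(type = sample(prop_types, 1L))
      }), vapply(take, function(p) curie_local(p$id), ""))
      nms <- names(rules)
      n_req <- sample.int(length(nms) + 1L, 1L) - 1L
      required <- if (n_req > 0L) nms[seq_len(n_req)] else character()
      rest <- setdiff(nms, required)
      recommended <- if (length(rest) && stats::runif(1) < 0.5) rest[1] else character()
      classes[[i]]$validation <- validation_ruleset(rules, required, recommended)
    }
    schema_document(namespace, ctx, classes, properties)
  })
}

DEFECT_KINDS <- c("missing_required", "wrong_type", "cardinality_breach",
                  "ontology_breach")

wrong_type_value <- function(rule) {
  type <- unlist(rule$type)[1]
  switch(type,
    string = 12345L,
    number = "not a number",
    integer = "not an integer",
    boolean = "not a boolean",
    object = "plain free text",
    array = "bare scalar",
    NULL)
}

is_ontology_rule <- function(rule) {
  !is.null(rule$properties$identifier$pattern) &&
    identical(unlist(rule$type)[1], "object")
}

applicable_defects <- function(compiled) {
  props <- compiled$properties
  scalar_typed <- names(props)[vapply(props, function(r) {
    !is.null(r$type) && !identical(unlist(r$type)[1], "array")
  }, logical(1))]
  typed <- names(props)[vapply(props, function(r) !is.null(r$type), logical(1))]
  onto <- names(props)[vapply(props, is_ontology_rule, logical(1))]
  list(
    missing_required = compiled$required,
    wrong_type = intersect(typed, compiled$required),
    cardinality_breach = intersect(scalar_typed, compiled$required),
    ontology_breach = intersect(onto, compiled$required))
}

#' Sample a labeled corpus of valid and invalid instance documents
#'
#' Generates `n` instance documents for a compiled rule set. A fraction of
#' them is made invalid by injecting exactly one named defect into an
#' otherwise-valid instance: `missing_required` (a required key deleted),
#' `wrong_type` (a value replaced by one of the wrong JSON type),
#' `cardinality_breach` (a single-valued property wrapped in an array), or
#' `ontology_breach` (an ontology-constrained identifier replaced by free
#' text). Labels are ground truth by construction: [validate_document()]
#' must agree with them exactly.
#'
#' @param compiled A [compile_validation()] result with at least one
#'   required property.
#' @param n Number of instances.
#' @param invalid_fraction Fraction in `[0, 1]` to corrupt.
#' @param seed Integer seed; the corpus is deterministic per seed.
#' @return A list of records `list(instance, valid, defect)`, where `defect`
#'   is `NA` for valid instances.
#' @export
sample_documents <- function(compiled, n, invalid_fraction = 0.5, seed = 1L) {
  sf_assert(n >= 1L, "generate_error", "n must be >= 1")
  sf_assert(invalid_fraction >= 0 && invalid_fraction <= 1, "generate_error",
            "invalid_fraction must be in [0, 1]")
  pool <- applicable_defects(compiled)
  usable <- DEFECT_KINDS[vapply(DEFECT_KINDS, function(k) length(pool[[k]]) > 0L, logical(1))]
  n_invalid <- round(n * invalid_fraction)
  sf_assert(n_invalid == 0L || length(usable) > 0L, "generate_error",
            "no defect is injectable for this rule set (no required, typed rules)")
  with_seed(seed, {
    flags <- sample(c(rep(FALSE, n_invalid), rep(TRUE, n - n_invalid)))
    inst_seeds <- sample.int(.Machine$integer.max - 1L, n)
    lapply(seq_len(n), function(i) {
      inst <- generate_example(compiled, seed = inst_seeds[i])
      if (flags[i]) {
        return(list(instance = inst, valid = TRUE, defect = NA_character_))
      }
      kind <- if (length(usable) == 1L) usable else sample(usable, 1L)
      targets <- pool[[kind]]
      nm <- if (length(targets) == 1L) targets else sample(targets, 1L)
      inst <- switch(kind,
        missing_required = { inst[[nm]] <- NULL; inst },
        wrong_type = { inst[[nm]] <- wrong_type_value(compiled$properties[[nm]]); inst },
        cardinality_breach = { inst[[nm]] <- list(inst[[nm]], inst[[nm]]); inst },
        ontology_breach = { inst[[nm]] <- list(identifier = "free text, not a curie"); inst })
      list(instance = inst, valid = FALSE, defect = kind)
    })
  })
}
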