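# a rule set compiled "by hand" for engine-level tests: no hierarchy involved
bare_compiled <- function(properties, required = character(), recommended = character()) {
  validation_ruleset(properties = properties, required = required,
                     recommended = recommended)
}

inst <- function(...) c(list(`@type` = "ex:Thing"), list(...))

test_that("marginality drives validity: required fails, recommended warns, optional is silent", {
  rs <- bare_compiled(list(name = list(type = "string"),
                           description = list(type = "string"),
                           url = list(type = "string")))
  rs <- set_marginality(rs, "name", "required")
  rs <- set_marginality(rs, "description", "recommended")
  r1 <- validate_document(inst(description = "d"), rs)
  expect_false(r1$valid)
  expect_identical(r1$violations[[1]]$path, "name")
  r2 <- validate_document(inst(name = "n"), rs)          # url optional+absent
  expect_true(r2$valid)
  expect_identical(vapply(r2$warnings, `[[`, "", "path"), "description")
  r3 <- validate_document(inst(name = "n", description = "d"), rs)
  expect_true(r3$valid)
  expect_length(r3$warnings, 0)
  expect_sf_error(set_marginality(rs, "nope", "required"), "ruleset_unknown_property")
})

test_that("cardinality many accepts scalar or non-empty list; one rejects lists", {
  rs <- bare_compiled(list(author = list(type = "string"),
                           citation = list(type = "string")))
  rs <- set_cardinality(rs, "author", "many")
  expect_true(validate_document(inst(author = "a"), rs)$valid)
  expect_true(validate_document(inst(author = list("a", "b")), rs)$valid)
  expect_false(validate_document(inst(author = list()), rs)$valid)       # minItems 1
  expect_false(validate_document(inst(citation = list("x", "y")), rs)$valid)
  # idempotent, not nested
  twice <- set_cardinality(set_cardinality(rs, "author", "many"), "author", "many")
  expect_identical(twice$properties$author, rs$properties$author)
  # round trip back to one
  back <- set_cardinality(rs, "author", "one")
  expect_identical(back$properties$author, list(type = "string"))
})

test_that("cardinality toggling never changes the required set, and vice versa", {
  rs <- bare_compiled(list(a = list(type = "string")), required = "a")
  rs2 <- set_cardinality(rs, "a", "many")
  expect_identical(rs2$required, rs$required)
  rs3 <- set_marginality(rs2, "a", "recommended")
  expect_identical(rs3$properties$a, rs2$properties$a)
})

test_that("many-cardinality acceptance equals the independent two-branch oracle", {
  types <- c("string", "integer", "boolean", "number")
  scalar_ok <- function(v, type) {
    switch(type,
      string = is.character(v) && length(v) == 1L,
      integer = is.numeric(v) && length(v) == 1L && !is.logical(v) && v == trunc(v),
      number = is.numeric(v) && length(v) == 1L && !is.logical(v),
      boolean = is.logical(v) && length(v) == 1L)
  }
  gen_value <- function() {
    pool <- list("txt", 3L, 2.5, TRUE, list(), list("a", "b"), list(1L, 2L),
                 list(TRUE, FALSE), list("a", 1L))
    pool[[sample.int(length(pool), 1L)]]
  }
  withr::with_seed(99, {
    for (i in 1:200) {
      type <- sample(types, 1L)
      rs <- set_cardinality(bare_compiled(stats::setNames(list(list(type = type)), "p")),
                            "p", "many")
      v <- gen_value()
      got <- validate_document(inst(p = v), rs)$valid
      want <- if (is.list(v)) {
        length(v) >= 1L && all(vapply(v, scalar_ok, logical(1), type = type))
      } else {
        scalar_ok(v, type)
      }
      expect_identical(got, want, info = paste(i, type, paste(class(v), collapse = ",")))
    }
  })
})

test_that("ontology constraints accept CURIE/IRI identifiers and match a regex oracle", {
  rs <- bare_compiled(list(infectiousAgent = list()))
  rs <- attach_ontology_constraint(rs, "infectiousAgent",
    list(prefix = "NCBITaxon", iri = "http://purl.obolibrary.org/obo/NCBITaxon_"))
  ok <- function(id) validate_document(inst(infectiousAgent = list(identifier = id)), rs)$valid
  expect_true(ok("NCBITaxon:2697049"))
  expect_true(ok("http://purl.obolibrary.org/obo/NCBITaxon_2697049"))
  expect_false(ok("SARS-CoV-2"))
  expect_false(validate_document(inst(infectiousAgent = "free text"), rs)$valid)
  expect_false(validate_document(inst(infectiousAgent = list(name = "x")), rs)$valid)
  # 100 random identifier strings vs an independent pattern oracle
  oracle <- function(id) {
    grepl("^NCBITaxon:[0-9]+$", id) ||
      startsWith(id, "http://purl.obolibrary.org/obo/NCBITaxon_") &&
        grepl("^[0-9]+$", sub("^http://purl\\.obolibrary\\.org/obo/NCBITaxon_", "", id))
  }
  withr::with_seed(7, {
    pieces <- c("NCBITaxon:", "NCBITaxon", "http://purl.obolibrary.org/obo/NCBITaxon_",
                "taxon:", "", "x")
    for (i in 1:100) {
      id <- paste0(sample(pieces, 1L),
                   paste(sample(c(0:9, letters[1:3], " "),
                                sample.int(6, 1L), replace = TRUE), collapse = ""))
      expect_identical(ok(id), oracle(id), info = id)
    }
  })
  expect_sf_error(attach_ontology_constraint(rs, "infectiousAgent", list()), "ruleset_error")
})

test_that("compilation unions required sets up the ancestor chain, child-most rule wins", {
  ctx <- tiny_context()
  parent_rs <- validation_ruleset(list(a = list(type = "string"),
                                       shared = list(type = "string")),
                                  required = "a")
  child_rs <- validation_ruleset(list(b = list(type = "integer"),
                                      shared = list(type = "integer")),
                                 required = "b")
  doc <- schema_document("ex", ctx,
    classes = list(class_definition("ex:P", validation = parent_rs),
                   class_definition("ex:C", sub_class_of = "ex:P", validation = child_rs)),
    properties = list(property_definition("ex:a", "ex:P"),
                      property_definition("ex:shared", "ex:P"),
                      property_definition("ex:b", "ex:C")))
  g <- build_class_graph(doc)
  compiled <- compile_validation(g, list(doc), "ex:C")
  expect_setequal(compiled$required, c("a", "b"))
  expect_identical(compiled$properties$shared, list(type = "integer"))
  # identity for a class with no ancestor validation
  solo <- compile_validation(g, list(doc), "ex:P")
  expect_setequal(solo$required, "a")
})

test_that("compilation rejects rules for properties outside the effective set", {
  ctx <- tiny_context()
  rs <- validation_ruleset(list(ghost = list(type = "string")))
  doc <- schema_document("ex", ctx,
                         classes = list(class_definition("ex:A", validation = rs)))
  g <- build_class_graph(doc)
  expect_sf_error(compile_validation(g, list(doc), "ex:A"), "ruleset_error")
})

test_that("unsupported keywords fail loudly at construction", {
  expect_sf_error(validation_ruleset(list(p = list(type = "string", maxLength = 3))),
                  "unsupported_keyword")
  expect_sf_error(validation_ruleset(list(p = list(type = "stringy"))), "ruleset_error")
  expect_sf_error(validation_ruleset(list(p = list(enum = list()))), "ruleset_error")
  expect_sf_error(validation_ruleset(list(p = list(`$ref` = "#/definitions/none"))),
                  "ruleset_error")
  expect_sf_error(validation_ruleset(list(p = list()), required = "q"), "ruleset_error")
  expect_sf_error(validation_ruleset(list(p = list()), required = "p", recommended = "p"),
                  "ruleset_error")
})

test_that("the compiled Outbreak Dataset ruleset meta-validates and drives reports", {
  docs <- core_and_outbreak()
  g <- build_class_graph(docs)
  compiled <- compile_validation(g, docs, "outbreak:Dataset")  # errors if meta-invalid
  good <- generate_example(compiled, seed = 11)
  expect_true(validate_document(good, compiled)$valid)
  bad <- good
  bad$infectiousAgent <- NULL
  rep <- validate_document(bad, compiled)
  expect_false(rep$valid)
  expect_identical(vapply(rep$violations, `[[`, "", "path"), "infectiousAgent")
  # @type mismatch is a violation, not an exception
  wrong <- good
  wrong$`@type` <- "schema:Dataset"
  expect_false(validate_document(wrong, compiled)$valid)
  expect_sf_error(validate_document("not an object", compiled), "instance_error")
})

test_that("generated examples always validate and lose validity with any required key", {
  for (seed in 1:10) {
    docs <- list(core_vocabulary(),
                 random_schema(200 + seed, n_classes = 5, n_props = 8, p_validation = 1))
    g <- suppressWarnings(build_class_graph(docs))
    for (id in names(docs[[2]]$classes)) {
      compiled <- compile_validation(g, docs, id)
      if (length(compiled$required) == 0L) next
      ex <- generate_example(compiled, seed = seed * 13L)
      expect_true(validate_document(ex, compiled)$valid, info = paste(seed, id))
      for (req in compiled$required) {
        mutated <- ex
        mutated[[req]] <- NULL
        expect_false(validate_document(mutated, compiled)$valid,
                     info = paste(seed, id, req))
      }
    }
  }
})

test_that("example generation is deterministic per seed and honors enum/pattern/format", {
  rs <- bare_compiled(
    list(status = list(enum = list("active", "completed")),
         taxid = list(type = "string", pattern = "^NCBITaxon:[0-9]+$"),
         date = list(type = "string", format = "date"),
         n = list(type = "integer")),
    required = c("status", "taxid", "date", "n"))
  attr(rs, "class_id") <- "ex:Thing"
  e1 <- generate_example(rs, seed = 5)
  e2 <- generate_example(rs, seed = 5)
  expect_identical(e1, e2)
  expect_true(e1$status %in% c("active", "completed"))
  expect_match(e1$taxid, "^NCBITaxon:[0-9]+$")
  expect_match(e1$date, "^[0-9]{4}-[0-9]{2}-[0-9]{2}$")
  expect_true(validate_document(e1, rs)$valid)
  # empty ruleset -> only @context and @type
  empty <- validation_ruleset()
  attr(empty, "class_id") <- "ex:Thing"
  expect_identical(names(generate_example(empty, seed = 1)), c("@context", "@type"))
})

test_that("exported JSON Schema is standalone draft-07", {
  docs <- core_and_outbreak()
  g <- build_class_graph(docs)
  compiled <- compile_validation(g, docs, "outbreak:Dataset")
  txt <- export_json_schema(compiled)
  parsed <- jsonlite::fromJSON(txt, simplifyVector = FALSE)
  expect_identical(parsed$`$schema`, "http://json-schema.org/draft-07/schema#")
  expect_identical(parsed$title, "outbreak:Dataset")
  expect_true(all(c("name", "infectiousAgent") %in% unlist(parsed$required)))
  expect_true("infectiousAgent" %in% names(parsed$properties))
})
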