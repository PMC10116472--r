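demo_request <- function(namespace = "covid", ...) {
  extension_request(
    base = "schema:Dataset", namespace = namespace, name = "Dataset",
    new_properties = list(list(name = "infectiousAgent", range = "schema:Thing",
                               description = "Pathogen studied.")),
    selected = c("name", "description"),
    validation = list(name = list(type = "string"),
                      description = list(type = "string"),
                      infectiousAgent = list(type = "object")),
    required = c("name", "infectiousAgent"),
    recommended = "description", ...)
}

test_that("extending schema:Dataset adds infectiousAgent on top of the inherited set", {
  core <- core_vocabulary()
  ext <- extend_class(list(core), demo_request())
  expect_identical(ext$classes[["covid:Dataset"]]$sub_class_of, "schema:Dataset")
  g <- build_class_graph(list(core, ext))
  view <- effective_properties(g, list(core, ext), "covid:Dataset")
  base_view <- effective_properties(g, list(core, ext), "schema:Dataset")
  expect_setequal(names(view$properties),
                  c(names(base_view$properties), "infectiousAgent"))
  # validation covers exactly selected + new
  expect_setequal(names(ext$classes[["covid:Dataset"]]$validation$properties),
                  c("name", "description", "infectiousAgent"))
})

test_that("pure subclassing inherits the base's effective set unchanged", {
  core <- core_vocabulary()
  req <- extension_request("schema:HowTo", "lab", "Protocol")
  ext <- extend_class(list(core), req)
  g <- build_class_graph(list(core, ext))
  expect_identical(
    names(effective_properties(g, list(core, ext), "lab:Protocol")$properties),
    names(effective_properties(g, list(core, ext), "schema:HowTo")$properties))
  expect_null(ext$classes[["lab:Protocol"]]$validation)
})

test_that("extension from a two-parent base matches the traversal oracle", {
  ctx <- context_map(dual = "https://example.org/dual/", schema = "https://schema.org/")
  dual <- schema_document("dual", ctx,
    classes = list(class_definition("dual:Mix",
                                    sub_class_of = c("schema:Dataset", "schema:HowTo"))),
    properties = list(property_definition("dual:own", "dual:Mix")))
  core <- core_vocabulary()
  req <- extension_request("dual:Mix", "kid", "Thing2",
    new_properties = lapply(1:5, function(i) list(name = paste0("extra", i))))
  ext <- extend_class(list(core, dual), req)
  docs <- list(core, dual, ext)
  g <- build_class_graph(docs)
  got <- vapply(effective_properties(g, docs, "kid:Thing2")$properties, `[[`, "", "id")
  ora <- oracle_effective_names(docs, "kid:Thing2")
  expect_identical(got[order(names(got))], ora[order(names(ora))])
})

test_that("extension is pure: base documents and base definitions are untouched", {
  core <- core_vocabulary()
  before <- serialize_schema(core)
  ext <- extend_class(list(core), demo_request())
  expect_identical(serialize_schema(core), before)
  # nothing from the base is copied into the extension document
  expect_identical(names(ext$classes), "covid:Dataset")
  expect_identical(names(ext$properties), "covid:infectiousAgent")
})

test_that("extension requests are checked: unknown base, collisions, bad selections", {
  core <- core_vocabulary()
  expect_sf_error(
    extend_class(list(core), extension_request("schema:Nope", "x", "Y")),
    "graph_unknown_class")
  expect_sf_error(
    extend_class(list(core), extension_request("schema:Dataset", "schema", "Dataset")),
    "request_collision")
  expect_sf_error(
    extend_class(list(core),
                 extension_request("schema:Dataset", "x", "Y", selected = "notAProp")),
    "request_error")
  expect_sf_error(
    extend_class(list(core),
                 extension_request("schema:Dataset", "x", "Y",
                                   selected = "name",
                                   new_properties = list(list(name = "name")))),
    "request_error")
})

test_that("extension requests round-trip through YAML config files", {
  path <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(
    base = "schema:Dataset", namespace = "covid", name = "Dataset",
    selected = list("name"),
    new_properties = list(list(name = "infectiousAgent", range = "schema:Thing")),
    validation = list(name = list(type = "string"),
                      infectiousAgent = list(type = "object")),
    required = list("name", "infectiousAgent")), path)
  req <- read_extension_request(path)
  ext <- extend_class(list(core_vocabulary()), req)
  expect_identical(names(ext$classes), "covid:Dataset")
})

test_that("merging per-class documents keeps each class exactly once, in order", {
  ob <- build_outbreak_schema()  # itself a merge of 22 per-class documents
  expect_length(ob$classes, 22)
  expect_identical(anyDuplicated(names(ob$classes)), 0L)
  # merging a document with itself changes nothing
  expect_identical(serialize_schema(merge_schemas(list(ob, ob), "outbreak")),
                   serialize_schema(ob))
})

test_that("merge is idempotent on canonical form and obeys the set-union oracle", {
  docs <- lapply(1:4, function(i) {
    random_schema(100 + i, n_classes = 3, n_props = 4, namespace = paste0("ns", i))
  })
  shared_ctx <- context_map(all = "https://example.org/all/")
  docs <- c(list(schema_document("all", shared_ctx)), docs)
  merged <- merge_schemas(docs, "all")
  expect_identical(serialize_schema(merge_schemas(list(merged), "all")),
                   serialize_schema(merged))
  expect_length(merged$classes,
                length(unique(unlist(lapply(docs, function(d) names(d$classes))))))
  expect_length(merged$properties,
                length(unique(unlist(lapply(docs, function(d) names(d$properties))))))
})

test_that("merge refuses conflicting definitions and conflicting prefixes", {
  a <- schema_document("ex", tiny_context(), list(class_definition("ex:A")))
  b <- schema_document("ex", tiny_context(),
                       list(class_definition("ex:A", sub_class_of = "schema:Thing")))
  expect_sf_error(merge_schemas(list(a, b), "ex"), "merge_conflict")
  c1 <- schema_document("ex", context_map(ex = "https://example.org/ex/"))
  c2 <- schema_document("ex", context_map(ex = "https://elsewhere.org/ex/"))
  expect_sf_error(merge_schemas(list(c1, c2), "ex"), "context_conflict")
})

test_that("authored documents round-trip and graph-build", {
  core <- core_vocabulary()
  ext <- extend_class(list(core), demo_request())
  txt <- serialize_schema(ext)
  expect_identical(serialize_schema(parse_schema(txt)), txt)
  g <- build_class_graph(list(core, ext))
  expect_true(is_rooted_in_schemaorg(g, "covid:Dataset"))
})
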