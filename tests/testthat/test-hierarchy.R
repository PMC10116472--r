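test_that("the class graph covers core + Outbreak and every Outbreak class has a parent", {
  docs <- core_and_outbreak()
  g <- build_class_graph(docs)
  ob_ids <- names(docs[[2]]$classes)
  expect_true(all(ob_ids %in% g$nodes))
  expect_true(all(vapply(ob_ids, function(id) length(g$parents[[id]]) >= 1L, logical(1))))
  expect_length(g$dangling, 0)
})

test_that("a single parentless class yields one node and no edges", {
  doc <- schema_document("ex", tiny_context(), list(class_definition("ex:Alone")))
  g <- build_class_graph(doc)
  expect_identical(g$nodes, "ex:Alone")
  expect_length(unlist(g$parents), 0)
  expect_identical(ancestor_chain(g, "ex:Alone"), list(character()))
})

test_that("subclass cycles are rejected with an error naming the cycle", {
  ctx <- tiny_context()
  doc <- schema_document("ex", ctx, list(
    class_definition("ex:A", sub_class_of = "ex:B"),
    class_definition("ex:B", sub_class_of = "ex:C"),
    class_definition("ex:C", sub_class_of = "ex:A")))
  err <- tryCatch(build_class_graph(doc), graph_cycle = function(e) e)
  expect_s3_class(err, "graph_cycle")
  expect_setequal(err$cycle, c("ex:A", "ex:B", "ex:C"))
})

test_that("dangling parents warn at build and are dead ends for rootedness", {
  doc <- schema_document("ex", tiny_context(), list(
    class_definition("ex:A", sub_class_of = "schema:Thing")))
  expect_warning(g <- build_class_graph(doc), "dangling")
  expect_identical(g$dangling, "schema:Thing")
  # the parent is *named* schema:Thing but not defined: not rooted
  expect_false(is_rooted_in_schemaorg(g, "ex:A"))
  # chains still terminate at the dangling parent
  expect_identical(ancestor_chain(g, "ex:A"), list("schema:Thing"))
})

test_that("outbreak:Protocol chains through schema:HowTo to schema:Thing", {
  docs <- core_and_outbreak()
  g <- build_class_graph(docs)
  chains <- ancestor_chain(g, "outbreak:Protocol")
  expect_identical(chains,
                   list(c("schema:HowTo", "schema:CreativeWork", "schema:Thing")))
  expect_identical(ancestor_chain(g, "schema:Thing"), list(character()))
  expect_sf_error(ancestor_chain(g, "ex:Nope"), "graph_unknown_class")
})

test_that("ancestor chains agree with exhaustive igraph path enumeration", {
  for (seed in 1:30) {
    docs <- random_docs_for_graph(seed, n_classes = 2L + seed %% 10L)
    g <- suppressWarnings(build_class_graph(docs))
    ids <- names(docs[[2]]$classes)
    for (id in ids) {
      got <- sort(unique(vapply(ancestor_chain(g, id), paste, "", collapse = " > ")))
      expect_identical(got, oracle_chain_set(docs, id), info = paste(seed, id))
    }
  }
})

test_that("effective properties match the naive union-with-override oracle", {
  for (seed in 31:55) {
    docs <- random_docs_for_graph(seed, n_classes = 2L + seed %% 8L)
    g <- suppressWarnings(build_class_graph(docs))
    for (id in names(docs[[2]]$classes)) {
      view <- effective_properties(g, docs, id)
      got <- vapply(view$properties, `[[`, "", "id")
      expect_identical(got[order(names(got))],
                       oracle_effective_names(docs, id)[order(names(oracle_effective_names(docs, id)))],
                       info = paste(seed, id))
    }
  }
})

test_that("shadowing resolves child-most first on a 3-level chain", {
  ctx <- tiny_context()
  # B-level definition outranks C-level when local names collide
  doc2 <- schema_document("ex", ctx,
    classes = list(class_definition("ex:C"),
                   class_definition("ex:B", sub_class_of = "ex:C"),
                   class_definition("ex:A", sub_class_of = "ex:B")),
    properties = list(
      property_definition("ex:shade", "ex:C", label = "C def"),
      property_definition("ex:shade2", "ex:B", label = "B def")))
  # construct the collision through separate documents sharing a local name
  docB <- schema_document("exb", context_map(exb = "https://example.org/exb/",
                                             ex = "https://example.org/ex/"),
    properties = list(property_definition("exb:shade", "ex:B", label = "B def")))
  g2 <- build_class_graph(doc2)
  view2 <- effective_properties(g2, list(doc2, docB), "ex:A")
  expect_identical(view2$properties[["shade"]]$id, "exb:shade")
  expect_identical(view2$contributed_by[["shade"]], "ex:B")
})

test_that("effective properties are monotone along every subclass edge", {
  docs <- c(core_and_outbreak(), list(random_schema(77, n_classes = 8, n_props = 12)))
  g <- suppressWarnings(build_class_graph(docs))
  for (child in g$nodes) {
    child_names <- names(effective_properties(g, docs, child)$properties)
    for (parent in g$parents[[child]]) {
      if (!parent %in% g$nodes) next
      parent_names <- names(effective_properties(g, docs, parent)$properties)
      expect_true(all(parent_names %in% child_names),
                  info = paste(child, "vs", parent))
    }
  }
})

test_that("rootedness follows defined ancestor chains into the schema namespace", {
  docs <- core_and_outbreak()
  g <- build_class_graph(docs)
  for (id in names(docs[[2]]$classes)) expect_true(is_rooted_in_schemaorg(g, id))
  iso <- schema_document("priv", context_map(priv = "https://example.org/priv/"),
                         list(class_definition("priv:Island")))
  g2 <- build_class_graph(c(docs, list(iso)))
  expect_false(is_rooted_in_schemaorg(g2, "priv:Island"))
})

test_that("a class is rooted through a single Schema.org ancestor even among private parents", {
  ctx <- context_map(priv = "https://example.org/priv/", schema = "https://schema.org/")
  doc <- schema_document("priv", ctx, list(
    class_definition("priv:Base"),
    class_definition("priv:Mixed", sub_class_of = c("priv:Base", "schema:Thing"))))
  g <- build_class_graph(list(core_vocabulary(), doc))
  expect_true(is_rooted_in_schemaorg(g, "priv:Mixed"))
  expect_false(is_rooted_in_schemaorg(g, "priv:Base"))
})

test_that("the class tree renders as text and as parseable JSON adjacency", {
  docs <- core_and_outbreak()
  g <- build_class_graph(docs)
  txt <- render_class_tree(g, "outbreak:ClinicalTrial")
  expect_match(txt, "schema:MedicalStudy")
  adj <- jsonlite::fromJSON(render_class_tree(g, "outbreak:ClinicalTrial", format = "json"),
                            simplifyVector = FALSE)
  expect_identical(adj$class, "outbreak:ClinicalTrial")
  expect_identical(unlist(adj$parents[["outbreak:ClinicalTrial"]]), "schema:MedicalStudy")
})
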