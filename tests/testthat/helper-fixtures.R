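# Shared fixtures and independent oracles. Oracles deliberately take a
# different algorithmic route than the implementation they check.

tiny_context <- function() context_map(ex = "https://example.org/ex/",
                                       schema = "https://schema.org/")

# A -> B -> schema:Thing, with one shadowed property local name
tiny_doc <- function() {
  ctx <- tiny_context()
  classes <- list(
    class_definition("ex:B", sub_class_of = "schema:Thing"),
    class_definition("ex:A", sub_class_of = "ex:B"))
  props <- list(
    property_definition("ex:size", domain_includes = "ex:B"),
    property_definition("ex:color", domain_includes = "ex:B"),
    property_definition("ex:sizeA", domain_includes = "ex:A",
                        label = "size (A)"))
  schema_document("ex", ctx, classes, props)
}

core_and_outbreak <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- list(core_vocabulary(), build_outbreak_schema())
    }
    cache
  }
})

# --- inheritance oracles -----------------------------------------------------

# igraph-based exhaustive root-path enumeration (independent of the package's
# recursive chain walker); returns the set of ancestor chains as strings
oracle_chain_set <- function(docs, class_id) {
  skip_if_not_installed("igraph")
  edges <- character()
  nodes <- character()
  for (doc in docs) {
    for (cls in doc$classes) {
      nodes <- union(nodes, cls$id)
      for (p in cls$sub_class_of) edges <- c(edges, cls$id, p)
    }
  }
  all_ids <- union(nodes, edges)
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges[c(TRUE, FALSE)], to = edges[c(FALSE, TRUE)]),
    directed = TRUE, vertices = data.frame(name = all_ids))
  # dangling parents (not defined as classes) terminate chains
  termini <- all_ids[vapply(all_ids, function(v) {
    !v %in% nodes || igraph::degree(g, v, mode = "out") == 0L
  }, logical(1))]
  chains <- character()
  for (t in termini) {
    paths <- igraph::all_simple_paths(g, from = class_id, to = t, mode = "out")
    for (p in paths) {
      ids <- igraph::V(g)$name[as.integer(p)]
      chains <- c(chains, paste(ids[-1], collapse = " > "))
    }
  }
  if (class_id %in% termini) chains <- c(chains, "")
  sort(unique(chains))
}

# naive union-with-override traversal: full preorder sequence with
# duplicates, dedup first occurrence, first property definition wins
oracle_effective_names <- function(docs, class_id) {
  parents <- list(); defined <- character()
  all_props <- list()
  for (doc in docs) {
    for (cls in doc$classes) {
      parents[[cls$id]] <- cls$sub_class_of
      defined <- c(defined, cls$id)
    }
    all_props <- c(all_props, unname(doc$properties))
  }
  preorder <- function(id) {
    out <- id
    for (p in parents[[id]]) if (p %in% defined) out <- c(out, preorder(p))
    out
  }
  order <- unique(preorder(class_id))
  eff <- character()  # local name -> property id
  for (cid in order) {
    for (prop in all_props) {
      if (!cid %in% prop$domain_includes) next
      nm <- sub("^[^:]+:", "", prop$id)
      if (!nm %in% names(eff)) eff[[nm]] <- prop$id
    }
  }
  eff
}

random_docs_for_graph <- function(seed, n_classes) {
  list(core_vocabulary(),
       random_schema(seed, n_classes = n_classes,
                     n_props = max(4L, n_classes), namespace = "rnd"))
}

expect_sf_error <- function(expr, class) {
  expect_error(expr, class = class)
}
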