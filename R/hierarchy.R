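# Class graph and property inheritance. Classes form a multi-parent DAG
# (Schema.org allows multiple inheritance); precedence for name collisions is
# child-most first, then left-parent first, realized as a preorder
# depth-first linearization with first-occurrence deduplication.

#' Build the class graph over a set of schema documents
#'
#' Collects every class from `docs` into one directed graph (child to
#' parents, parent order preserved). Parents that are named but defined
#' nowhere are recorded as *dangling* with a warning — users can work before
#' importing every dependency — but count as dead ends for rootedness.
#' Subclass cycles are rejected with an error naming the cycle, as is the
#' same class id defined differently in two documents.
#'
#' @param docs A [schema_document()] or list of them.
#' @return A `class_graph`: nodes, parent adjacency, dangling ids, and a map
#'   from class id to originating namespace.
#' @export
build_class_graph <- function(docs) {
  if (inherits(docs, "schema_document")) docs <- list(docs)
  nodes <- character(); parents <- list(); source_ns <- character(); seen_def <- list()
  for (doc in docs) {
    for (cls in doc$classes) {
      node_json <- class_node_json(cls)
      if (cls$id %in% nodes) {
        sf_assert(identical(seen_def[[cls$id]], node_json), "graph_duplicate_class",
                  paste0("class '", cls$id, "' is defined differently in two documents"))
        next
      }
      nodes <- c(nodes, cls$id)
      parents[[cls$id]] <- cls$sub_class_of
      source_ns[[cls$id]] <- doc$namespace
      seen_def[[cls$id]] <- node_json
    }
  }
  dangling <- setdiff(unique(unlist(parents)), nodes)
  if (length(dangling)) {
    warning(paste0("dangling parent class(es): ", paste(dangling, collapse = ", ")),
            call. = FALSE)
  }
  graph <- structure(list(nodes = nodes, parents = parents,
                          dangling = dangling, source = source_ns),
                     class = "class_graph")
  cyc <- find_cycle(graph)
  if (!is.null(cyc)) {
    sf_error("graph_cycle", paste0("subclass cycle: ", paste(cyc, collapse = " -> ")),
             cycle = cyc)
  }
  graph
}

# DFS three-color cycle detection; returns the cycle's members or NULL
find_cycle <- function(graph) {
  color <- stats::setNames(rep(0L, length(graph$nodes)), graph$nodes)
  stack <- character()
  found <- NULL
  visit <- function(v) {
    if (!is.null(found)) return()
    color[[v]] <<- 1L
    stack <<- c(stack, v)
    for (p in graph$parents[[v]]) {
      if (!p %in% graph$nodes) next
      if (color[[p]] == 1L) {
        i <- match(p, stack)
        found <<- stack[i:length(stack)]
        return()
      }
      if (color[[p]] == 0L) visit(p)
      if (!is.null(found)) return()
    }
    color[[v]] <<- 2L
    stack <<- stack[-length(stack)]
  }
  for (v in graph$nodes) if (color[[v]] == 0L) visit(v)
  found
}

check_in_graph <- function(graph, class_id) {
  sf_assert(inherits(graph, "class_graph"), "graph_error", "expected a class_graph")
  sf_assert(class_id %in% graph$nodes, "graph_unknown_class",
            paste0("unknown class '", class_id, "'"))
  invisible(TRUE)
}

#' Enumerate a class's ancestor chains
#'
#' Returns every chain of ancestors from the class up to a root, one chain
#' per distinct path through the multi-parent graph, enumerated depth-first
#' and left-parent first. Each chain excludes the class itself and ends at a
#' parentless class (a dangling parent, being undefined, terminates its
#' chain). A root class yields a single empty chain.
#'
#' @param graph A [build_class_graph()] result.
#' @param class_id CURIE of the class.
#' @return List of character vectors of ancestor ids.
#' @export
ancestor_chain <- function(graph, class_id) {
  check_in_graph(graph, class_id)
  walk <- function(id) {
    ps <- graph$parents[[id]]
    if (length(ps) == 0L) return(list(character()))
    out <- list()
    for (p in ps) {
      if (!p %in% graph$nodes) {
        out[[length(out) + 1L]] <- p  # dangling terminus
      } else {
        for (tail in walk(p)) out[[length(out) + 1L]] <- c(p, tail)
      }
    }
    out
  }
  walk(class_id)
}

# child-most-first, left-parent-first precedence order over defined classes
linearize_ancestry <- function(graph, class_id) {
  seen <- character()
  visit <- function(id) {
    if (id %in% seen) return()
    seen <<- c(seen, id)
    for (p in graph$parents[[id]]) if (p %in% graph$nodes) visit(p)
  }
  visit(class_id)
  seen
}

#' Compute a class's effective (inherited-inclusive) properties
#'
#' The effective property set of a class is the union of every property
#' whose `domain_includes` names the class or any of its ancestors. When two
#' properties share a local name, the child-most definition wins; among
#' parents, the left-most wins.
#'
#' @inheritParams ancestor_chain
#' @param docs The documents the graph was built from (property source).
#' @return An `effective_class_view`: the class id, its ancestor
#'   linearization, and a named list mapping property local names to
#'   [property_definition()]s.
#' @export
effective_properties <- function(graph, docs, class_id) {
  check_in_graph(graph, class_id)
  if (inherits(docs, "schema_document")) docs <- list(docs)
  all_props <- do.call(c, c(lapply(docs, function(d) unname(d$properties)), list(list())))
  lineage <- linearize_ancestry(graph, class_id)
  eff <- list(); contributed_by <- character()
  for (cid in lineage) {
    for (prop in all_props) {
      if (!cid %in% prop$domain_includes) next
      nm <- curie_local(prop$id)
      if (!nm %in% names(eff)) {
        eff[[nm]] <- prop
        contributed_by[[nm]] <- cid
      }
    }
  }
  structure(list(class_id = class_id, ancestors = lineage[-1],
                 properties = eff, contributed_by = contributed_by),
            class = "effective_class_view")
}

#' Is a class rooted in Schema.org?
#'
#' `TRUE` iff the class itself, or any ancestor reachable through defined
#' classes, belongs to the `schema` namespace. Dangling parents are dead
#' ends: a parent merely *named* `schema:Something` does not count until its
#' definition is loaded.
#'
#' @inheritParams ancestor_chain
#' @return Logical scalar.
#' @export
is_rooted_in_schemaorg <- function(graph, class_id) {
  check_in_graph(graph, class_id)
  any(curie_prefix(linearize_ancestry(graph, class_id)) == "schema")
}

#' Render a class graph as an indented tree or adjacency list
#'
#' @inheritParams ancestor_chain
#' @param format `"text"` for an indented ancestor tree, `"json"` for a
#'   machine-readable adjacency object.
#' @return A single string.
#' @export
render_class_tree <- function(graph, class_id, format = c("text", "json")) {
  format <- match.arg(format)
  check_in_graph(graph, class_id)
  if (format == "json") {
    lineage <- c(class_id, linearize_ancestry(graph, class_id)[-1])
    adj <- lapply(stats::setNames(lineage, lineage), function(id) {
      as.list(graph$parents[[id]] %||% character())
    })
    return(to_json_canonical(list(class = class_id, parents = adj,
                                  dangling = as.list(intersect(unlist(adj), graph$dangling)))))
  }
  lines <- character()
  walk <- function(id, depth) {
    tag <- if (!id %in% graph$nodes) " [dangling]" else ""
    lines <<- c(lines, paste0(strrep("  ", depth), id, tag))
    if (id %in% graph$nodes) for (p in graph$parents[[id]]) walk(p, depth + 1L)
  }
  walk(class_id, 0L)
  paste0(paste(lines, collapse = "\n"), "\n")
}

#' @export
print.class_graph <- function(x, ...) {
  cat(sprintf("<class_graph> %d class(es), %d edge(s), %d dangling parent(s)\n",
              length(x$nodes), length(unlist(x$parents)), length(x$dangling)))
  invisible(x)
}

#' @export
print.effective_class_view <- function(x, ...) {
  cat(sprintf("<effective_class_view> %s: %d effective propert%s (%d inherited)\n",
              x$class_id, length(x$properties),
              if (length(x$properties) == 1L) "y" else "ies",
              sum(x$contributed_by != x$class_id)))
  invisible(x)
}
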