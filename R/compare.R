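#' Compare the property sets of two to four classes
#'
#' Partitions the (by default inherited-inclusive) effective property names
#' of the given classes into those shared by every class and those unique to
#' each, plus pairwise intersection sizes — the registry's "what properties
#' are unique to each and what properties they share" view. Comparison is
#' over property local names so that an inherited `name` unifies across
#' namespaces; local names that stand for different full property IRIs
#' across the compared classes are listed in `name_collisions`.
#'
#' @param graph A [build_class_graph()] covering every class.
#' @param docs The documents the graph was built from.
#' @param class_ids Character vector of 2 to 4 class CURIEs.
#' @param inherited Include inherited properties (default) or own-domain
#'   properties only.
#' @return A `comparison_result` with fields `class_ids`, `shared`,
#'   `unique` (named list), `pairwise` (matrix of intersection sizes), and
#'   `name_collisions`.
#' @export
compare_classes <- function(graph, docs, class_ids, inherited = TRUE) {
  k <- length(class_ids)
  sf_assert(k >= 2L && k <= 4L, "compare_limit",
            paste0("can compare 2 to 4 classes, got ", k))
  for (id in class_ids) check_in_graph(graph, id)
  if (inherits(docs, "schema_document")) docs <- list(docs)

  prop_sets <- lapply(class_ids, function(id) {
    if (inherited) {
      view <- effective_properties(graph, docs, id)
      stats::setNames(vapply(view$properties, `[[`, "", "id"), names(view$properties))
    } else {
      own <- Filter(function(p) id %in% p$domain_includes,
                    do.call(c, c(lapply(docs, function(d) unname(d$properties)), list(list()))))
      stats::setNames(vapply(own, `[[`, "", "id"),
                      vapply(own, function(p) curie_local(p$id), ""))
    }
  })
  names(prop_sets) <- class_ids
  name_sets <- lapply(prop_sets, names)

  shared <- sort(Reduce(intersect, name_sets))
  unique_sets <- lapply(seq_len(k), function(i) {
    sort(setdiff(name_sets[[i]], unlist(name_sets[-i])))
  })
  names(unique_sets) <- class_ids

  pairwise <- matrix(0L, k, k, dimnames = list(class_ids, class_ids))
  for (i in seq_len(k)) {
    for (j in seq_len(k)) {
      pairwise[i, j] <- length(intersect(name_sets[[i]], name_sets[[j]]))
    }
  }

  all_names <- unique(unlist(name_sets))
  collisions <- Filter(function(nm) {
    iris <- unique(unlist(lapply(prop_sets, function(s) unname(s[nm]))))
    length(iris[!is.na(iris)]) > 1L
  }, all_names)

  structure(list(class_ids = class_ids, shared = shared, unique = unique_sets,
                 pairwise = pairwise, name_collisions = sort(unlist(collisions))),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("<comparison_result> %s\n", paste(x$class_ids, collapse = " vs ")))
  cat(sprintf("  shared (%d): %s\n", length(x$shared), paste(x$shared, collapse = ", ")))
  for (id in x$class_ids) {
    cat(sprintf("  unique to %s (%d): %s\n", id, length(x$unique[[id]]),
                paste(x$unique[[id]], collapse = ", ")))
  }
  if (length(x$name_collisions)) {
    cat("  note: same local name, different property IRI:",
        paste(x$name_collisions, collapse = ", "), "\n")
  }
  invisible(x)
}

comparison_to_json <- function(x) {
  to_json_canonical(list(
    class_ids = as.list(x$class_ids),
    shared = as.list(x$shared),
    unique = lapply(x$unique, as.list),
    pairwise = apply(x$pairwise, 1, as.list, simplify = FALSE),
    name_collisions = as.list(x$name_collisions)))
}
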