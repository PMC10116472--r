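# Example-markup generation: build an instance document that satisfies a
# compiled rule set ("create markup using a schema"). Deterministic per seed.

# synthesize a string matching a restricted anchored regex: literals,
# character classes with +/{n} repetition, \d, and top-level alternation
# (first alternative wins). Anything fancier raises.
synthesize_pattern <- function(pattern) {
  pat <- strsplit(pattern, "|", fixed = TRUE)[[1]][1]
  pat <- sub("^\\^", "", sub("\\$$", "", pat))
  out <- ""
  i <- 1L
  n <- nchar(pat)
  emit_class <- function(chars, i) {
    reps <- 1L
    if (i <= n && substr(pat, i, i) == "+") {
      reps <- sample(1L:6L, 1L); i <- i + 1L
    } else if (i <= n && substr(pat, i, i) == "*") {
      reps <- sample(0L:4L, 1L); i <- i + 1L
    } else if (i <= n && substr(pat, i, i) == "{") {
      close <- regexpr("}", substr(pat, i, n), fixed = TRUE)
      sf_assert(close > 0L, "generate_error", paste0("unsupported pattern: ", pattern))
      spec <- substr(pat, i + 1L, i + close - 2L)
      reps <- as.integer(strsplit(spec, ",")[[1]][1])
      i <- i + close
    }
    list(text = paste(sample(chars, reps, replace = TRUE), collapse = ""), i = i)
  }
  while (i <= n) {
    ch <- substr(pat, i, i)
    if (ch == "[") {
      close <- regexpr("]", substr(pat, i + 1L, n), fixed = TRUE)
      sf_assert(close > 0L, "generate_error", paste0("unsupported pattern: ", pattern))
      body <- substr(pat, i + 1L, i + close - 1L)
      chars <- expand_char_class(body)
      res <- emit_class(chars, i + close + 1L)
      out <- paste0(out, res$text); i <- res$i
    } else if (ch == "\\") {
      nxt <- substr(pat, i + 1L, i + 1L)
      if (nxt == "d") {
        res <- emit_class(as.character(0:9), i + 2L)
        out <- paste0(out, res$text); i <- res$i
      } else {
        out <- paste0(out, nxt); i <- i + 2L
      }
    } else if (ch %in% c("(", ")", "?")) {
      sf_error("generate_error", paste0("unsupported pattern construct in: ", pattern))
    } else {
      out <- paste0(out, ch); i <- i + 1L
    }
  }
  out
}

expand_char_class <- function(body) {
  chars <- character(); i <- 1L; n <- nchar(body)
  while (i <= n) {
    if (i + 2L <= n && substr(body, i + 1L, i + 1L) == "-") {
      lo <- utf8ToInt(substr(body, i, i)); hi <- utf8ToInt(substr(body, i + 2L, i + 2L))
      chars <- c(chars, vapply(lo:hi, intToUtf8, ""))
      i <- i + 3L
    } else {
      chars <- c(chars, substr(body, i, i)); i <- i + 1L
    }
  }
  chars
}

generate_value <- function(rule, defs, name) {
  if (!is.null(rule$`$ref`)) {
    target <- sub("^#/definitions/", "", rule$`$ref`)
    return(generate_value(defs[[target]], defs, name))
  }
  if (!is.null(rule$enum)) return(rule$enum[[sample.int(length(rule$enum), 1L)]])
  if (!is.null(rule$oneOf)) return(generate_value(rule$oneOf[[1]], defs, name))
  if (!is.null(rule$anyOf)) return(generate_value(rule$anyOf[[1]], defs, name))
  type <- unlist(rule$type)[1] %||% if (!is.null(rule$properties)) "object" else "string"
  switch(type,
    string = {
      if (!is.null(rule$pattern)) return(synthesize_pattern(rule$pattern))
      if (!is.null(rule$format)) {
        return(switch(rule$format,
          date = sprintf("20%02d-%02d-%02d", sample.int(30, 1L), sample.int(12, 1L),
                         sample.int(28, 1L)),
          `date-time` = sprintf("20%02d-%02d-%02dT%02d:%02d:00Z", sample.int(30, 1L),
                                sample.int(12, 1L), sample.int(28, 1L),
                                sample.int(23, 1L), sample.int(59, 1L)),
          uri = paste0("https://example.org/", name, "/", sample.int(1e6, 1L)),
          email = paste0(name, sample.int(1e4, 1L), "@example.org"),
          paste0("example ", name, " ", sample.int(1e6, 1L))))
      }
      paste0("example ", name, " ", sample.int(1e6, 1L))
    },
    number = round(stats::runif(1, 0, 1000), 2),
    integer = sample.int(1000L, 1L),
    boolean = sample(c(TRUE, FALSE), 1L),
    null = NULL,
    array = {
      item_rule <- rule$items %||% list(type = "string")
      k <- max(1L, rule$minItems %||% 1L)
      lapply(seq_len(k), function(i) generate_value(item_rule, defs, name))
    },
    object = {
      obj <- list()
      req <- as.character(unlist(rule$required))
      for (nm in union(req, names(rule$properties))) {
        sub_rule <- rule$properties[[nm]] %||% list(type = "string")
        obj[[nm]] <- generate_value(sub_rule, defs, nm)
      }
      if (length(obj) == 0L) obj <- list(name = paste0("example ", name))
      obj
    },
    sf_error("generate_error", paste0("cannot generate a value of type '", type, "'")))
}

#' Generate example markup satisfying a compiled rule set
#'
#' Builds an instance document containing `"@context"`, `"@type"`, and a
#' value for every required property that satisfies its rule. Deterministic
#' for a fixed seed; the output always passes [validate_document()] against
#' the same rule set.
#'
#' @param compiled A [compile_validation()] result.
#' @param class_id Class CURIE for `"@type"`; defaults to the rule set's
#'   `class_id` attribute.
#' @param seed Integer seed.
#' @param include_recommended Also populate recommended properties.
#' @return A named list (JSON object).
#' @export
generate_example <- function(compiled, class_id = NULL, seed = 1L,
                             include_recommended = FALSE) {
  sf_assert(inherits(compiled, "validation_ruleset"), "ruleset_error",
            "compiled must be a validation_ruleset")
  class_id <- class_id %||% attr(compiled, "class_id")
  sf_assert(is_scalar_string(class_id), "generate_error",
            "generate_example needs a class id (none compiled in)")
  ctx <- attr(compiled, "context")
  if (is.null(ctx)) ctx <- c(schema = "https://schema.org/")
  keep <- unique(c(curie_prefix(class_id), "schema"))
  ctx <- ctx[names(ctx) %in% keep]
  if (length(ctx) == 0L) ctx <- c(schema = "https://schema.org/")
  with_seed(seed, {
    inst <- list(`@context` = as.list(stats::setNames(unname(ctx), names(ctx))),
                 `@type` = class_id)
    targets <- compiled$required
    if (include_recommended) targets <- c(targets, compiled$recommended)
    for (nm in targets) {
      inst[[nm]] <- generate_value(compiled$properties[[nm]], compiled$definitions, nm)
    }
    inst
  })
}
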