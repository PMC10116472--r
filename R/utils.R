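# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

# conditions carry a machine-readable class so callers (registry, CLI) can branch
sf_error <- function(class, msg, ...) {
  stop(errorCondition(msg, ..., class = c(class, "schemaforge_error", "error", "condition")))
}

sf_assert <- function(ok, class, msg) {
  if (!isTRUE(ok)) sf_error(class, msg)
  invisible(TRUE)
}

# run code under a seed without disturbing the caller's RNG state
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

# jsonlite maps an empty named list to {}; an unnamed one to []
as_json_map <- function(x) {
  if (length(x) == 0L) structure(list(), names = character(0)) else x
}

is_scalar_string <- function(x) is.character(x) && length(x) == 1L && !is.na(x)

to_json_canonical <- function(x) {
  paste0(jsonlite::toJSON(x, auto_unbox = TRUE, pretty = 2, digits = NA, null = "null"), "\n")
}
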