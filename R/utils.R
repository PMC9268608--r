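`%||%` <- function(x, y) if (is.null(x)) y else x

# Evaluate `expr` under a deterministic seed without disturbing the caller's
# RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

stopifnot_finite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(what, " must be finite numeric", call. = FALSE)
  }
  invisible(x)
}

# Recursively sort list names so serialized JSON is byte-stable across
# runs; named atomic vectors become named lists so their names survive as
# JSON object keys.
sort_keys <- function(x) {
  if (is.atomic(x) && !is.null(names(x))) x <- as.list(x)
  if (is.list(x) && !is.null(names(x)) && !is.data.frame(x)) {
    x <- x[order(names(x))]
    lapply(x, sort_keys)
  } else if (is.list(x) && !is.data.frame(x)) {
    lapply(x, sort_keys)
  } else {
    x
  }
}
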