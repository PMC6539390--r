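# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Sets the seed for the duration of `expr` and restores the caller's RNG
#' state afterwards, so seeded operations do not disturb the global stream.
#' With `seed = NULL` the expression runs on the current stream unchanged.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number or NULL")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Draw n sub-seeds from the current stream (31-bit positive integers).
draw_seeds <- function(n) {
  sample.int(.Machine$integer.max - 1L, n)
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) stop(sprintf("'%s' must be finite", what), call. = FALSE)
  invisible(x)
}

# Tiny rolling-polynomial hash of a serialized R object; used to stamp
# report files so a bundle can be traced back to its configuration.
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, connection = NULL, version = 2L))
  h <- 0
  for (b in bytes) h <- (h * 257 + b + 1) %% 2147483647
  sprintf("%08x", h)
}
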