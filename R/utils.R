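# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so package functions that
#' accept a `seed` argument do not disturb the global random stream.
#'
#' @param seed integer seed, or NULL to use the current stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Deterministic sub-stream seeds derived from one master seed.
# Kept below 2^31 - 1 so they remain valid R integers.
sub_seed <- function(seed, k) {
  s <- (as.double(seed) %% 2147483647)
  as.integer((s * 1103515245 + 12345 + 97 * as.double(k)) %% 2147483647)
}

stop_param <- function(...) stop(..., call. = FALSE)

check_prob <- function(p, what) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop_param(what, " must lie in [0, 1] and be finite")
  invisible(p)
}

check_nonneg <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0))
    stop_param(what, " must be finite and non-negative")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
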