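# Internal helpers shared across modules.

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream; with seed = NULL the global stream is consumed as-is.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

check_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    stop_invalid("`%s` must be a single finite value > 0 (got %s)",
                 name, deparse(substitute(x)))
  invisible(x)
}

check_timepoints <- function(timepoints) {
  if (!is.numeric(timepoints) || length(timepoints) < 2L)
    stop_invalid("`timepoints` must contain at least two values (hours)")
  if (any(!is.finite(timepoints)))
    stop_invalid("`timepoints` must be finite")
  if (timepoints[1L] != 0)
    stop_invalid("`timepoints` must start at 0 h (got %g)", timepoints[1L])
  if (any(diff(timepoints) <= 0))
    stop_invalid("`timepoints` must be strictly ascending")
  invisible(timepoints)
}
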