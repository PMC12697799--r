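# internal helpers

# evaluate expr under a local RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    set.seed(NULL)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# derive a stage-specific child seed from a global seed; stays below 2^31
deriveSeed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + 104729 * as.numeric(i)) %% 2147483647)
}

assertScalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a finite numeric scalar", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be positive", name), call. = FALSE)
  if (nonneg && x < 0)
    stop(sprintf("'%s' must be non-negative", name), call. = FALSE)
  invisible(x)
}

# nearest integer with a commensurability check (value must be a near-exact
# multiple of step)
asGridUnits <- function(value, step, what) {
  r <- value / step
  if (any(abs(r - round(r)) > 1e-6))
    stop(sprintf("%s must be an integer multiple of the grid step (%g s)",
                 what, step), call. = FALSE)
  as.integer(round(r))
}
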