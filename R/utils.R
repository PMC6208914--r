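# internal helpers

# Run code with a temporary seed, restoring the caller's RNG state afterwards.
# seed = NULL runs in the ambient RNG stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a finite numeric scalar", name)
  if (x < lower || x > upper)
    stopf("'%s' = %g outside [%g, %g]", name, x, lower, upper)
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
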