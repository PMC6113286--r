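# Internal helpers shared across the package.

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored on exit. seed = NULL draws from the current stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1L)  # force RNG initialisation so the state can be restored
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_invalid <- function(...) {
  stop(..., call. = FALSE)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    stop_invalid(sprintf("'%s' must be a finite numeric scalar", name))
  }
  if (x < lower || x > upper) {
    stop_invalid(sprintf("'%s' must be in [%s, %s]", name,
                         format(lower), format(upper)))
  }
  invisible(x)
}
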