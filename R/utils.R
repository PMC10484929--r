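# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression with a local, restorable RNG state
#'
#' All stochastic generators in the package funnel their randomness through
#' this helper so that a single explicit seed fully determines the output and
#' the caller's global RNG state is left untouched.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

# Derive n child seeds (< 2^31) from one parent seed, deterministically.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max, n))
}

stop_brainfrac <- function(...) stop(..., call. = FALSE)

assert_that <- function(ok, msg) if (!isTRUE(ok)) stop_brainfrac(msg)

# Positive length-3 numeric, named or not; returns unnamed numeric(3).
as_triple <- function(x, what) {
  assert_that(is.numeric(x) && length(x) == 3L && all(is.finite(x)),
              sprintf("%s must be a finite numeric triple (y, x, z)", what))
  as.numeric(x)
}
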