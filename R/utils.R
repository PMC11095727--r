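#' Evaluate code under a fixed RNG seed without disturbing the global stream
#'
#' All stochastic generators in the package route their randomness through this
#' helper so that every operation is bit-reproducible given `(parameters, seed)`
#' and calling a generator never perturbs the caller's random state.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

# Derive a child seed from (seed, stream label); keeps derived seeds < 2^31.
# Arithmetic in doubles (exact below 2^53) to avoid integer overflow.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) * 48271 + as.numeric(stream)) %% 2147483562)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
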