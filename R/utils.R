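#' Create an isolated, resumable random-number stream
#'
#' Returns a function that evaluates a thunk under a private RNG state
#' seeded once with `seed`. Successive calls continue the same stream;
#' the caller's global RNG state is untouched. Used by the infinite batch
#' iterator so that training draws are reproducible without clobbering
#' user randomness.
#'
#' @param seed integer seed initialising the stream.
#' @return a function `f(thunk)` evaluating `thunk()` under the stream.
#' @keywords internal
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  state <- NULL
  function(thunk) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    if (is.null(state)) {
      set.seed(as.integer(seed))
    } else {
      assign(".Random.seed", state, envir = globalenv())
    }
    on.exit({
      state <<- get(".Random.seed", envir = globalenv())
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    thunk()
  }
}

# single scalar finite numeric check
is_number <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)

# stop() with a consistent prefix-free message, sprintf-style
abort_fmt <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
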