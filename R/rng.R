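#' Self-contained random number streams
#'
#' A small wrapper around R's RNG that gives each simulator object its own
#' private stream, so that simulations are pure functions of their seed and
#' never disturb (nor depend on) the global `.Random.seed`.
#'
#' @param seed Integer seed, or an existing `rng_stream` (returned unchanged).
#' @return An object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  if (inherits(seed, "rng_stream")) return(seed)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  env <- new.env(parent = emptyenv())
  old <- .globalenv_seed()
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", envir = globalenv())
  .restore_seed(old)
  class(env) <- "rng_stream"
  env
}

#' Evaluate a drawing function under a private RNG stream
#'
#' @param rng An `rng_stream`.
#' @param fn A function of no arguments performing the random draws.
#' @return The value of `fn()`; the stream's state is advanced.
#' @keywords internal
with_rng <- function(rng, fn) {
  stopifnot(inherits(rng, "rng_stream"))
  old <- .globalenv_seed()
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    .restore_seed(old)
  })
  fn()
}

# Derive a reproducible child seed; stays within 32-bit integer range.
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) %% 2147483647 * 48271 + index) %% 2147483563)
}

.globalenv_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
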