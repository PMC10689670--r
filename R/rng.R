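#' @name rng
#' @title Seeded random streams
#'
#' @description
#' All randomness in fragrl flows through explicit stream objects derived
#' from one root seed, so tree tie-breaks, policy initialization, episode
#' sampling and the mock docking engine are independently reproducible and
#' never disturb the caller's global `.Random.seed`.
NULL

#' Create a seeded random stream
#'
#' A small closure object around R's Mersenne-Twister whose state is saved
#' and restored around every draw, isolating it from the global RNG.
#'
#' @param seed integer seed (kept below 2^31)
#' @return an environment with `runif`, `rnorm`, `sample_int`, `sample_prob`
#'   and `derive(k)` (a child stream with a deterministic derived seed)
#' @export
rng_stream <- function(seed) {
  seed <- as.integer(abs(as.numeric(seed)) %% 2147483647)
  self <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv())
  set.seed(seed)
  self$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  draw <- function(fn) {
    force(fn)
    function(...) {
      outer <- get0(".Random.seed", envir = globalenv())
      assign(".Random.seed", self$state, envir = globalenv())
      on.exit({
        self$state <- get(".Random.seed", envir = globalenv())
        if (is.null(outer)) {
          rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", outer, envir = globalenv())
        }
      })
      fn(...)
    }
  }
  self$runif <- draw(stats::runif)
  self$rnorm <- draw(stats::rnorm)
  self$sample_int <- draw(function(n, size = 1L, replace = FALSE,
                                   prob = NULL) {
    sample.int(n, size = size, replace = replace, prob = prob)
  })
  # categorical draw from an explicit probability vector
  self$sample_prob <- draw(function(prob) {
    sample.int(length(prob), size = 1L, prob = prob)
  })
  self$derive <- function(k) {
    rng_stream((as.numeric(seed) * 48271 + as.numeric(k) * 9973) %% 2147483647)
  }
  self
}
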