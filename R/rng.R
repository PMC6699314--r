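#' Create an isolated random-number stream
#'
#' Returns a small stream object whose draws are independent of, and do not
#' disturb, R's global random state. Every stochastic operation in the
#' package (phantom synthesis, augmentation sampling, weight initialization,
#' epoch shuffling, dropout) draws from such a stream so that a single seed
#' reproduces a run bit-exactly.
#'
#' @param seed integer seed.
#' @return an object of class `hs_rng` with methods accessed through
#'   [rng_runif()], [rng_rnorm()], [rng_sample()].
#' @export
rng_new <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- get_global_seed()
  set.seed(as.integer(seed) %% .Machine$integer.max)
  e$state <- .Random.seed
  restore_global_seed(old)
  class(e) <- "hs_rng"
  e
}

get_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "hs_rng"))
  old <- get_global_seed()
  assign(".Random.seed", rng$state, envir = globalenv())
  on.exit({
    rng$state <- get(".Random.seed", envir = globalenv())
    restore_global_seed(old)
  })
  expr
}

#' @rdname rng_new
#' @param rng stream created by [rng_new()].
#' @param n number of draws.
#' @param min,max uniform bounds.
#' @export
rng_runif <- function(rng, n, min = 0, max = 1) with_rng(rng, runif(n, min, max))

#' @rdname rng_new
#' @param mean,sd normal parameters.
#' @export
rng_rnorm <- function(rng, n, mean = 0, sd = 1) with_rng(rng, rnorm(n, mean, sd))

#' @rdname rng_new
#' @param x vector to sample from, as in [sample()].
#' @param size sample size.
#' @param replace sample with replacement?
#' @export
rng_sample <- function(rng, x, size = length(x), replace = FALSE) {
  with_rng(rng, sample(x, size, replace = replace))
}

#' @rdname rng_new
#' @export
rng_spawn <- function(rng) {
  # Derive a child stream; used to give each phantom / minibatch item its
  # own reproducible sub-stream.
  rng_new(floor(rng_runif(rng, 1, 0, 2^31 - 1)))
}
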