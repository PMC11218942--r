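# Isolated, resumable RNG streams. Each stream owns its own .Random.seed
# state so that e.g. the per-epoch augmentation draw sequence is unaffected
# by how many random numbers weight initialization or data generation used.

#' Isolated RNG streams
#'
#' A stream owns its own `.Random.seed` state, so independent random
#' consumers (weight init, augmentation draws, image noise) do not perturb
#' each other's sequences. Draw with [rng_runif()], [rng_rnorm()],
#' [rng_sample()], [rng_rpois()].
#'
#' @param seed integer seed.
#' @return an `rng_stream` object (environment).
#' @export
rng_stream <- function(seed) {
  self <- new.env(parent = emptyenv())
  .rng_with_state(NULL, function() set.seed(seed), self)
  self
}

.rng_with_state <- function(state, fn, self) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  if (!is.null(state)) assign(".Random.seed", state, envir = globalenv())
  res <- fn()
  self$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  res
}

#' @rdname rng_stream
#' @param stream an `rng_stream`.
#' @param fn a function evaluated with the stream's RNG state active.
#' @export
rng_eval <- function(stream, fn) .rng_with_state(stream$state, fn, stream)

local({
  # attach convenience methods at load time via closures
})

#' @rdname rng_stream
#' @param n number of draws.
#' @param ... passed to the underlying stats function.
#' @export
rng_runif <- function(stream, n, ...) rng_eval(stream, function() stats::runif(n, ...))
#' @rdname rng_stream
#' @export
rng_rnorm <- function(stream, n, ...) rng_eval(stream, function() stats::rnorm(n, ...))
#' @rdname rng_stream
#' @param x,size,replace as in [sample()].
#' @export
rng_sample <- function(stream, x, size, replace = FALSE)
  rng_eval(stream, function() sample(x, size, replace = replace))
#' @rdname rng_stream
#' @param lambda Poisson mean.
#' @export
rng_rpois <- function(stream, n, lambda) rng_eval(stream, function() stats::rpois(n, lambda))

# a derived integer seed (stable, < 2^31) for per-case sub-streams
#' Derive a stable sub-seed from a master seed and labels
#' @param master_seed integer master seed.
#' @param ... labels (strings/numbers) identifying the consumer.
#' @return an integer seed below 2^31.
#' @export
derive_seed <- function(master_seed, ...) {
  parts <- c(master_seed, unlist(list(...)))
  h <- 0
  for (p in parts) {
    for (ch in utf8ToInt(paste0(p))) h <- (h * 31 + ch) %% 2147483563
  }
  as.integer(h + 1)
}
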