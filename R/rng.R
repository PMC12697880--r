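#' Independent reproducible random-number streams
#'
#' A run of the simulator draws from several conceptually independent sources
#' of randomness (cell-state noise, competency gating, gap-junction closure,
#' genome mutation, the evolutionary optimizer). Each source gets its own
#' stream so that enabling one mechanism never perturbs the draws of another:
#' paired runs that differ only in one mechanism share all other draws.
#'
#' A stream is a small environment holding its own copy of R's RNG state
#' (Mersenne-Twister). Draw functions swap the stream state into
#' `.Random.seed`, draw, and swap the previous global state back, so streams
#' never interfere with each other or with user code.
#'
#' @param seed integer seed for the stream (must be < 2^31).
#' @return an object of class `rng_stream`.
#' @examples
#' s <- rng_stream(1)
#' stream_rnorm(s, 3)
#' @export
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  class(e) <- "rng_stream"
  e
}

with_stream <- function(stream, fn) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  fn()
}

#' @rdname rng_stream
#' @param stream an `rng_stream`.
#' @param n number of draws.
#' @export
stream_rnorm <- function(stream, n) with_stream(stream, function() stats::rnorm(n))

#' @rdname rng_stream
#' @export
stream_runif <- function(stream, n) with_stream(stream, function() stats::runif(n))

#' @rdname rng_stream
#' @param x vector to sample from.
#' @param size sample size.
#' @export
stream_sample <- function(stream, x, size) {
  with_stream(stream, function() x[sample.int(length(x), size)])
}

#' Derive a reproducible child seed from a master seed and labels
#'
#' Hashes the master seed together with any number of string/integer labels
#' into a new 31-bit seed, so a single master seed can spawn named substreams
#' (e.g. one per generation/candidate/repetition during evolution).
#'
#' @param seed master integer seed.
#' @param ... labels (character or integer) identifying the substream.
#' @return an integer in `[0, 2^31 - 1)`.
#' @export
derive_seed <- function(seed, ...) {
  parts <- c(as.integer(seed),
             unlist(lapply(list(...), function(p) {
               if (is.character(p)) utf8ToInt(paste(p, collapse = "")) else as.integer(p)
             }), use.names = FALSE))
  m <- 2147483647
  h <- 17
  for (v in parts) h <- (h * 31 + (as.double(v) %% m)) %% m
  as.integer(h)
}

#' @export
print.rng_stream <- function(x, ...) {
  cat("<rng_stream>\n")
  invisible(x)
}
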