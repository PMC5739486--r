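#' @useDynLib ldctscn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats fft mvfft rnorm rpois runif sd var setNames
#' @importFrom utils write.csv
NULL

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's state afterwards.  With seed = NULL the global stream is used.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number", call. = FALSE)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Derive a stream of child seeds from one master seed, so that independent
# stages (phantom draws, photon noise, weight init, shuffling) never share a
# stream.  Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict && x <= min) stopf("'%s' must be > %g", name, min)
  if (!strict && x < min) stopf("'%s' must be >= %g", name, min)
  invisible(x)
}
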