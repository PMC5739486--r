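#' Simulate photon counts from a noiseless sinogram
#'
#' Under a monoenergetic source the measurement along ray i is
#' `z_i ~ Poisson(b0 * exp(-l_i) + r)`, where `l_i` is the line integral of
#' attenuation, `b0` the blank-scan photon count (uniform across rays) and
#' `r` the mean of the electronic noise floor. Lower `b0` means lower dose
#' and noisier data.
#'
#' @param sino a noiseless [sinogram()].
#' @param b0 blank-scan photons per ray (> 0); e.g. `1e5` for a standard
#'   low-dose level, `5e5` / `5e4` for milder / harsher ones.
#' @param r_mean mean electronic noise counts added to every ray (>= 0).
#' @param seed integer seed; fixed seed gives bit-identical counts.
#' @return an object of class `counts_measurement` with integer-valued
#'   `counts` (n_views x n_bins), `b0`, `r_mean` and the geometry.
#' @export
simulate_counts <- function(sino, b0, r_mean = 0, seed = NULL) {
  if (!inherits(sino, "sinogram")) stopf("'sino' must be a sinogram")
  if (sino$noisy) stopf("'sino' must be noiseless")
  if (!is.numeric(b0) || length(b0) != 1L || !is.finite(b0) || b0 <= 0)
    stopf("'b0' must be a single number > 0")
  check_number(r_mean, "r_mean", 0)
  lambda <- b0 * exp(-sino$values) + r_mean
  z <- with_seed(seed, rpois(length(lambda), lambda))
  counts <- matrix(as.numeric(z), nrow(sino$values), ncol(sino$values))
  structure(list(counts = counts, b0 = b0, r_mean = r_mean,
                 geometry = sino$geometry),
            class = "counts_measurement")
}

#' @export
print.counts_measurement <- function(x, ...) {
  cat(sprintf("counts_measurement: %d x %d rays, b0=%g, r=%g, counts in [%g, %g]\n",
              nrow(x$counts), ncol(x$counts), x$b0, x$r_mean,
              min(x$counts), max(x$counts)))
  invisible(x)
}

#' Log-transform photon counts into a noisy sinogram
#'
#' Estimates each line integral as `l_hat = log(b0 / max(z - r, eps))` with
#' an `eps`-count floor so photon-starved rays (z near or below the
#' electronic floor) stay finite, then clips negatives (rays measuring more
#' than the blank scan) to zero.
#'
#' @param meas a [simulate_counts()] result.
#' @param eps count floor before the log (default 1).
#' @return a noisy [sinogram()].
#' @export
counts_to_sinogram <- function(meas, eps = 1) {
  if (!inherits(meas, "counts_measurement"))
    stopf("'meas' must be a counts_measurement")
  check_number(eps, "eps", 0, strict = TRUE)
  l <- log(meas$b0 / pmax(meas$counts - meas$r_mean, eps))
  l[l < 0] <- 0
  sinogram(l, meas$geometry, noisy = TRUE)
}
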