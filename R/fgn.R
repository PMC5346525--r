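#' Autocovariance of fractional Gaussian noise
#'
#' Autocovariance function of unit-variance fractional Gaussian noise (fGn)
#' with Hurst exponent `hurst` at integer lags `lags`:
#' \deqn{\gamma(k) = \tfrac{1}{2}(|k+1|^{2H} - 2|k|^{2H} + |k-1|^{2H}).}
#'
#' @param lags integer vector of lags (>= 0)
#' @param hurst Hurst exponent in (0, 1)
#' @return numeric vector of autocovariances
#' @keywords internal
fgn_acvf <- function(lags, hurst) {
  stopifnot(all(lags >= 0))
  h2 <- 2 * hurst
  0.5 * (abs(lags + 1)^h2 - 2 * abs(lags)^h2 + abs(lags - 1)^h2)
}

#' Simulate exact fractional Gaussian noise
#'
#' Generates a stationary, zero-mean fractional Gaussian noise series with
#' exactly the target autocovariance, using circulant embedding
#' (Davies-Harte). fGn is the increment process of fractional Brownian
#' motion; its Hurst exponent controls long memory: `hurst = 0.5` is white
#' noise, `hurst > 0.5` persistent, `hurst < 0.5` anti-persistent.
#'
#' The circulant embedding of the autocovariance must be nonnegative
#' definite; for `hurst` close to 1 combined with very short series the
#' embedding can fail, in which case an error is raised rather than falling
#' back to an approximate construction.
#'
#' @param length number of time points (>= 16)
#' @param hurst target Hurst exponent, in the open interval (0, 1)
#' @param seed integer seed; the same (length, hurst, seed) triple always
#'   returns the identical series
#' @return numeric vector of length `length` with zero expectation and unit
#'   marginal variance
#' @examples
#' x <- simulate_fgn(256, 0.8, seed = 1)
#' @export
simulate_fgn <- function(length, hurst, seed) {
  stopifnot(length >= 16, hurst > 0, hurst < 1)
  n <- as.integer(length)
  # Circulant embedding of the (n x n) Toeplitz covariance into size 2(n-1):
  # first row gamma_0 .. gamma_{n-1}, gamma_{n-2} .. gamma_1.
  g <- fgn_acvf(0:(n - 1L), hurst)
  first_row <- c(g, g[seq(n - 1L, 2L)])
  m <- base::length(first_row)
  lambda <- Re(stats::fft(first_row))
  tol <- 1e-8 * max(abs(lambda))
  if (any(lambda < -tol)) {
    stop("circulant embedding is not nonnegative definite for hurst = ",
         hurst, " at length ", n,
         "; increase the series length or lower the Hurst exponent")
  }
  lambda[lambda < 0] <- 0
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))
  z <- stats::rnorm(m) + 1i * stats::rnorm(m)
  w <- stats::fft(sqrt(lambda / m) * z, inverse = FALSE)
  Re(w)[seq_len(n)]
}
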