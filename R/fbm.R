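#' Simulate fractional Gaussian noise
#'
#' Exact synthesis of fractional Gaussian noise (fGn) with Hurst exponent
#' `H` by circulant embedding of the autocovariance (Davies-Harte method).
#' The returned series has unit-variance increments in distribution; scale
#' as needed.
#'
#' @param n Number of samples (>= 2).
#' @param hurst Hurst exponent, in (0, 1).
#' @param seed Optional integer seed; when given, the draw is reproducible
#'   and the caller's RNG state is untouched.
#' @return Numeric vector of length `n`.
#' @seealso [fbm_sim()] for the cumulated (motion) path.
#' @export
#' @examples
#' x <- fgn_sim(1024, hurst = 0.7, seed = 1)
fgn_sim <- function(n, hurst, seed = NULL) {
  stopifnot(n >= 2, hurst > 0, hurst < 1)
  draw <- function() {
    m <- 2^ceiling(log2(2 * (n - 1)))
    k <- 0:(m / 2)
    # fGn autocovariance gamma(k) = (|k+1|^2H - 2|k|^2H + |k-1|^2H)/2
    g <- 0.5 * (abs(k + 1)^(2 * hurst) - 2 * abs(k)^(2 * hurst) +
                  abs(k - 1)^(2 * hurst))
    lambda <- Re(fft(c(g, rev(g[2:(m / 2)]))))
    # tiny negative eigenvalues can occur from round-off; clip
    lambda[lambda < 0] <- 0
    z <- complex(real = rnorm(m), imaginary = rnorm(m))
    z[1] <- complex(real = sqrt(2) * Re(z[1]), imaginary = 0)
    z[m / 2 + 1] <- complex(real = sqrt(2) * Re(z[m / 2 + 1]), imaginary = 0)
    z[(m / 2 + 2):m] <- Conj(z[seq(m / 2, 2)])
    Re(fft(sqrt(lambda / (2 * m)) * z))[1:n] * sqrt(2)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a fractional Brownian motion path
#'
#' Cumulative sum of [fgn_sim()] increments. The graph of fractional
#' Brownian motion with Hurst exponent `H` has box-counting dimension
#' `2 - H`, which makes this the reference process for validating the
#' fractal-dimension estimator.
#'
#' @inheritParams fgn_sim
#' @return Numeric vector of length `n`.
#' @export
#' @examples
#' path <- fbm_sim(4096, hurst = 0.5, seed = 42)
fbm_sim <- function(n, hurst, seed = NULL) {
  cumsum(fgn_sim(n, hurst, seed = seed))
}
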