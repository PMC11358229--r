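#' The ex-Gaussian distribution
#'
#' Density, random generation and moments for the ex-Gaussian distribution,
#' the convolution of a Normal(mu, sigma) and an Exponential with mean tau.
#' This is the standard distributional model for reaction times in speeded
#' tasks: the Gaussian component absorbs perceptual/motor variability and
#' the exponential tail absorbs the slow decision-related skew.
#'
#' The density is evaluated in log space.  For small `tau` the textbook
#' closed form cancels catastrophically, so beyond a cutoff the evaluation
#' switches to an asymptotic Mills-ratio expansion that collapses to the
#' limiting Gaussian density; absolute accuracy is better than 1e-8
#' throughout.
#'
#' @param x vector of quantiles (seconds).
#' @param mu mean of the Gaussian component (seconds).
#' @param sigma standard deviation of the Gaussian component (seconds, > 0).
#' @param tau mean of the exponential component (seconds, > 0).
#' @param log logical; return log-density?
#' @return `dexgauss`: densities (per second). `rexgauss`: draws (seconds).
#'   `exgauss_moments`: list with `mean` (= mu + tau) and `variance`
#'   (= sigma^2 + tau^2).
#' @examples
#' dexgauss(0, mu = 0, sigma = 1, tau = 1)       # ~ 0.2616
#' exgauss_moments(mu = 1.58, sigma = 0.51, tau = 0.57)$mean   # 2.15 s
#' @export
dexgauss <- function(x, mu, sigma, tau, log = FALSE) {
  check_exgauss_params(mu, sigma, tau)
  lp <- exgauss_lpdf_cpp(as.numeric(x), mu, sigma, tau)
  if (log) lp else exp(lp)
}

#' @rdname dexgauss
#' @param n number of draws.
#' @param positive_only logical; reject-and-redraw non-positive values so
#'   that draws are usable as reaction times.  The ex-Gaussian has support
#'   on the whole real line, but at empirically sensible parameter values
#'   the mass below zero is negligible; the rejection exists so that the
#'   synthetic-data generator can never emit a non-positive RT.
#' @export
rexgauss <- function(n, mu, sigma, tau, positive_only = FALSE) {
  check_exgauss_params(mu, sigma, tau)
  stopifnot(n >= 1)
  x <- rnorm(n, mu, sigma) + rexp(n, rate = 1 / tau)
  if (positive_only) {
    bad <- which(x <= 0)
    guard <- 0L
    while (length(bad) > 0 && guard < 1000L) {
      x[bad] <- rnorm(length(bad), mu, sigma) + rexp(length(bad), rate = 1 / tau)
      bad <- bad[x[bad] <= 0]
      guard <- guard + 1L
    }
    if (length(bad) > 0)
      stop("could not draw positive reaction times at mu=", mu,
           ", sigma=", sigma, ", tau=", tau)
  }
  x
}

#' @rdname dexgauss
#' @export
exgauss_moments <- function(mu, sigma, tau) {
  check_exgauss_params(mu, sigma, tau)
  list(mean = mu + tau, variance = sigma^2 + tau^2)
}

check_exgauss_params <- function(mu, sigma, tau) {
  if (!is.finite(mu) || !is.finite(sigma) || !is.finite(tau))
    stop("ex-Gaussian parameters must be finite")
  if (sigma <= 0) stop("sigma must be > 0")
  if (tau <= 0) stop("tau must be > 0")
  invisible(TRUE)
}
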