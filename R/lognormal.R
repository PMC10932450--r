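#' Calibrate a log-normal distribution from median and IQR
#'
#' Given a median `m` and interquartile range `IQR` of a positive quantity,
#' returns the unique log-normal parameters with that median and IQR:
#' `mu = ln(m)` and, from `Q75 - Q25 = 2 m sinh(z75 sigma)`,
#' `sigma = asinh(IQR / (2 m)) / z75`, with `z75` the standard normal 0.75
#' quantile. This is how the published per-class median (IQR) summaries of
#' the summed Ca/K peak areas are turned into sampling distributions.
#'
#' @param median median in AU, > 0.
#' @param iqr interquartile range in AU, > 0 (a zero IQR would collapse the
#'   class to a point mass and is rejected).
#' @return list of class `lognormal_params` with fields `mu`, `sigma`.
#' @export
calibrate_lognormal <- function(median, iqr) {
  stopifnot(is.numeric(median), is.numeric(iqr),
            length(median) == 1L, length(iqr) == 1L)
  if (!is.finite(median) || median <= 0) {
    stop("median must be a positive finite number")
  }
  if (!is.finite(iqr) || iqr <= 0) {
    stop("iqr must be a positive finite number (degenerate class otherwise)")
  }
  z75 <- stats::qnorm(0.75)
  structure(list(mu = log(median), sigma = asinh(iqr / (2 * median)) / z75),
            class = "lognormal_params")
}

#' Quantile function of calibrated parameters
#' @param params a [calibrate_lognormal()] result.
#' @param p probabilities.
#' @return quantiles in AU.
#' @export
qlognormal <- function(params, p) {
  stats::qlnorm(p, meanlog = params$mu, sdlog = params$sigma)
}

# Draw n values from the calibrated log-normal by inverse-CDF sampling.
#
# Truncation is symmetric: a total probability mass of 1 - trunc_q is removed
# equally from both tails (u ranges over [(1-q)/2, (1+q)/2]), so truncation
# cannot shift the median, while still capping line amplitudes.
#
# Stratified sampling (the default for n > 1) places exactly one draw in each
# of n equal-probability strata, in random order with a random position
# within its stratum: the empirical quantiles of a class then match the
# calibrated distribution to O(1/n) instead of O(1/sqrt(n)), so a synthetic
# cohort of a few hundred shots actually carries the published medians and
# IQRs it was calibrated to. Uses the current RNG stream.
rlognormal_trunc <- function(n, params, trunc_q = 1, stratified = TRUE) {
  stopifnot(trunc_q > 0, trunc_q <= 1)
  if (n == 0L) return(numeric(0))
  lo <- (1 - trunc_q) / 2
  hi <- (1 + trunc_q) / 2
  if (stratified && n > 1L) {
    u <- lo + (hi - lo) * (sample.int(n) - stats::runif(n)) / n
  } else {
    u <- stats::runif(n, lo, hi)
  }
  qlognormal(params, u)
}
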