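#' Intensity-histogram features
#'
#' The 11 first-order features of the discretized ROI intensity histogram:
#' mean, variance (population), standard deviation, skewness, excess
#' kurtosis, median, minimum, maximum, range, energy (uniformity,
#' \eqn{\sum p_i^2}) and entropy (\eqn{-\sum p_i \log_2 p_i}). Following the
#' 274-feature catalog arithmetic, these are computed once per image from the
#' linear discretization at Nb = 64 rather than per texture variant.
#'
#' @param x numeric vector of ROI intensities (non-empty).
#' @param spec [discretization_spec()] applied before computing the
#'   histogram statistics; default linear, 64 bins.
#' @return named numeric vector of 11 features; entropy in bits, bounded by
#'   `log2(n_bins)`; energy in `(0, 1]`.
#' @export
intensity_features <- function(x, spec = discretization_spec("linear", 64L)) {
  if (length(x) == 0L) stop("empty intensity list")
  lev <- discretize(x, spec)
  n <- length(lev)
  mu <- mean(lev)
  v <- mean((lev - mu)^2)
  s <- sqrt(v)
  skew <- if (s > 0) mean((lev - mu)^3) / s^3 else 0
  kurt <- if (s > 0) mean((lev - mu)^4) / s^4 - 3 else 0
  p <- tabulate(lev, nbins = spec$n_bins) / n
  p <- p[p > 0]
  c(mean_histogram = mu,
    variance_histogram = v,
    standard_deviation_histogram = s,
    skewness_histogram = skew,
    kurtosis_histogram = kurt,
    median_histogram = median(lev),
    minimum_histogram = min(lev),
    maximum_histogram = max(lev),
    range_histogram = diff(range(lev)),
    energy_histogram = sum(p^2),
    entropy_histogram = -sum(p * log2(p)))
}
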