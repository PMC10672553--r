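#' First-order (intensity histogram) descriptors
#'
#' Seventeen descriptors of the masked intensity distribution, computed on
#' the raw (unquantized) in-mask intensities: mean, std and variance
#' (population, divisor n), skewness and kurtosis (Pearson moment
#' coefficients; a normal sample has kurtosis 3; both defined as 0 for a
#' constant sample), median, percentiles p10/p25/p75/p90 (linear
#' interpolation between order statistics), min, max, range, IQR
#' (p75 - p25), MAD (mean absolute deviation from the mean), and
#' histogram energy / entropy over 32 equal-width bins spanning the masked
#' range (entropy in bits, with 0 log 0 = 0).
#'
#' @param sample an [roi_sample()].
#' @return Named numeric vector of length 17 (names `fo_*`).
#' @examples
#' roi <- roi_sample(matrix(rnorm(256), 16, 16), matrix(TRUE, 16, 16),
#'                   "s", "INJ", "STIR")
#' first_order_features(roi)[c("fo_mean", "fo_mad", "fo_entropy")]
#' @export
first_order_features <- function(sample) {
  stopifnot(inherits(sample, "roi_sample"))
  x <- masked_values(sample)
  n <- length(x)
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skw <- if (m2 > 0) m3 / m2^1.5 else 0
  krt <- if (m2 > 0) m4 / m2^2 else 0
  qs <- unname(quantile(x, c(0.10, 0.25, 0.50, 0.75, 0.90), type = 7))
  bins <- tabulate(bin_equal_width(x, 32L), nbins = 32L)
  f <- bins / n
  out <- c(
    fo_energy   = sum(f^2),
    fo_entropy  = entropy_bits(f),
    fo_iqr      = qs[4] - qs[2],
    fo_kurtosis = krt,
    fo_mad      = mean(abs(x - mu)),
    fo_max      = max(x),
    fo_mean     = mu,
    fo_median   = qs[3],
    fo_min      = min(x),
    fo_p10      = qs[1],
    fo_p25      = qs[2],
    fo_p75      = qs[4],
    fo_p90      = qs[5],
    fo_range    = max(x) - min(x),
    fo_skewness = skw,
    fo_std      = sqrt(m2),
    fo_variance = m2
  )
  out[FO_NAMES]
}
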