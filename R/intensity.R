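#' Intensity-distribution features of a masked PET volume
#'
#' First-order statistics over the SUV values inside the mask. Skewness
#' and kurtosis use biased central moments (`m_k / n`); kurtosis is the
#' excess kurtosis (`m4 / m2^2 - 3`). A zero-variance region returns 0
#' for both standardized moments.
#'
#' @param volume A [pet_volume()].
#' @param mask A `tumor_mask` or logical array.
#' @return Named list of features.
#' @export
#' @examples
#' v <- pet_volume(array(c(1, 1, 1, 5, 0, 0, 0, 0), c(2, 2, 2)))
#' m <- array(c(rep(TRUE, 4), rep(FALSE, 4)), c(2, 2, 2))
#' intensity_features(v, m)$intensity_skewness  # ~1.1547
intensity_features <- function(volume, mask) {
  flags <- if (inherits(mask, "tumor_mask")) mask$flags else mask
  x <- volume$values[flags]
  n <- length(x)
  assert_that(n >= 1, "empty mask")
  mu <- mean(x)
  m2 <- mean((x - mu)^2)
  m3 <- mean((x - mu)^3)
  m4 <- mean((x - mu)^4)
  skew <- if (m2 > 0) m3 / m2^1.5 else 0
  kurt <- if (m2 > 0) m4 / m2^2 - 3 else 0
  q <- unname(quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  list(
    intensity_mean = mu,
    intensity_variance = m2,
    intensity_sd = sqrt(m2),
    intensity_skewness = skew,
    intensity_kurtosis = kurt,
    intensity_median = q[3],
    intensity_min = min(x),
    intensity_p10 = q[1],
    intensity_p90 = q[5],
    intensity_max = max(x),
    intensity_interquartile_range = q[4] - q[2],
    intensity_range = max(x) - min(x),
    intensity_mean_absolute_deviation = mean(abs(x - mu)),
    intensity_median_absolute_deviation = mean(abs(x - q[3])),
    intensity_energy = sum(x^2),
    intensity_rms = sqrt(mean(x^2)),
    intensity_cov = if (mu != 0) sqrt(m2) / mu else 0,
    intensity_quartile_coeff_dispersion =
      if ((q[4] + q[2]) != 0) (q[4] - q[2]) / (q[4] + q[2]) else 0
  )
}

#' Histogram features of a discretized region
#'
#' Computed over the occupied-level probabilities `p_i` of the
#' discretized gray levels. Uniformity is `sum(p_i^2)` (1 for a constant
#' region); entropy is `-sum(p_i log2 p_i)`.
#'
#' @param d A [discretize()]d region.
#' @return Named list of features.
#' @export
#' @examples
#' v <- pet_volume(array(rep(c(1, 2), 4), c(2, 2, 2)))
#' d <- discretize(v, array(TRUE, c(2, 2, 2)), "fbn", 2)
#' histogram_features(d)$discretized_intensity_uniformity  # 0.5
histogram_features <- function(d) {
  stopifnot(inherits(d, "discretized_roi"))
  lev <- d$levels[d$mask]
  counts <- tabulate(lev, nbins = max(lev))
  p <- counts / sum(counts)
  occ <- p > 0
  i <- seq_along(p)
  mu <- sum(i * p)
  v <- sum((i - mu)^2 * p)
  list(
    discretized_intensity_mean = mu,
    discretized_intensity_variance = v,
    discretized_intensity_uniformity = sum(p[occ]^2),
    discretized_intensity_entropy = -sum(p[occ] * log2(p[occ])),
    discretized_intensity_mode = which.max(counts),
    discretized_intensity_max_probability = max(p)
  )
}
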