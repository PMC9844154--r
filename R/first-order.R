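#' The 18 first-order intensity features
#'
#' Standard intensity statistics over the masked voxels. Entropy and
#' uniformity use the discretized gray-level histogram; all other statistics
#' use raw attenuation values. Total energy scales energy by the physical
#' voxel volume.
#'
#' @param volume a [voxel_volume()].
#' @param mask an [roi_mask()].
#' @param roi a `discretized_roi` from [discretize()] (histogram features).
#' @return named numeric vector of 18 features (prefixed `firstorder_`).
#' @export
first_order_features <- function(volume, mask, roi) {
  check_aligned(volume, mask)
  x <- as.numeric(volume)[mask]
  n <- length(x)
  vvox <- prod(vol_spacing(volume))
  q <- unname(quantile(x, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7))
  m <- mean(x)
  v <- mean((x - m)^2) # population variance, as is conventional for radiomics
  s <- sqrt(v)
  in_iqr <- x[x >= q[2] & x <= q[4]]
  rmad <- if (length(in_iqr)) mean(abs(in_iqr - mean(in_iqr))) else 0
  hist_p <- tabulate(roi$levels[mask], nbins = roi$ng) / n
  hp <- hist_p[hist_p > 0]
  skew <- if (s > 0) mean((x - m)^3) / s^3 else 0
  kurt <- if (s > 0) mean((x - m)^4) / s^4 else 0
  c(
    firstorder_energy = sum(x^2),
    firstorder_total_energy = vvox * sum(x^2),
    firstorder_entropy = -sum(hp * log2(hp)),
    firstorder_minimum = min(x),
    firstorder_p10 = q[1],
    firstorder_p90 = q[5],
    firstorder_maximum = max(x),
    firstorder_mean = m,
    firstorder_median = q[3],
    firstorder_interquartile_range = q[4] - q[2],
    firstorder_range = max(x) - min(x),
    firstorder_mean_absolute_deviation = mean(abs(x - m)),
    firstorder_robust_mean_absolute_deviation = rmad,
    firstorder_root_mean_squared = sqrt(mean(x^2)),
    firstorder_skewness = skew,
    firstorder_kurtosis = kurt,
    firstorder_variance = v,
    firstorder_uniformity = sum(hist_p^2)
  )
}
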