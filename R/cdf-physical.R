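#' The 5 cumulative-distribution-function features
#'
#' Shape descriptors of the empirical CDF of masked intensities after
#' min-max normalization to `[0, 1]`: area under the CDF, normalized
#' mean-minus-median, central slope of the CDF between the 25th and 75th
#' intensity percentiles, and the lower/upper tail fractions beyond two
#' standard deviations from the mean. A zero intensity range returns the
#' degenerate conventions (AUC 0.5, slope capped at `n`, zero asymmetry and
#' tails) with the `degenerate` attribute set.
#'
#' @param volume a [voxel_volume()].
#' @param mask an [roi_mask()].
#' @return named numeric vector of 5 features (prefixed `cdf_`).
#' @export
cdf_features <- function(volume, mask) {
  check_aligned(volume, mask)
  x <- as.numeric(volume)[mask]
  n <- length(x)
  if (n < 2) stop("CDF features need at least 2 masked voxels", call. = FALSE)
  rng <- range(x)
  degenerate <- diff(rng) == 0
  if (degenerate) {
    out <- c(
      cdf_auc = 0.5, cdf_mean_minus_median = 0,
      cdf_central_slope = as.numeric(n),
      cdf_lower_tail_fraction = 0, cdf_upper_tail_fraction = 0
    )
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  u <- (x - rng[1]) / diff(rng)
  us <- sort(u)
  # AUC of the empirical CDF on [0, 1]: integral of F(t) dt = 1 - mean(u)
  auc <- 1 - mean(u)
  q <- unname(quantile(u, c(0.25, 0.5, 0.75), type = 7))
  slope <- if (q[3] > q[1]) 0.5 / (q[3] - q[1]) else as.numeric(n)
  m <- mean(u)
  s <- sd(u)
  out <- c(
    cdf_auc = auc,
    cdf_mean_minus_median = m - q[2],
    cdf_central_slope = min(slope, as.numeric(n)),
    cdf_lower_tail_fraction = mean(u < m - 2 * s),
    cdf_upper_tail_fraction = mean(u > m + 2 * s)
  )
  attr(out, "degenerate") <- FALSE
  out
}

#' The 2 physical features
#'
#' Physical ROI volume in millilitres and a mass proxy in grams obtained by
#' converting attenuation to an approximate physical density,
#' `mass = volume_mL * mean(HU + 1000) / 1000`.
#'
#' @param volume a [voxel_volume()].
#' @param mask an [roi_mask()].
#' @param spacing voxel spacing in mm.
#' @return named numeric vector of 2 features (prefixed `physical_`).
#' @export
physical_features <- function(volume, mask, spacing = vol_spacing(volume)) {
  check_aligned(volume, mask)
  x <- as.numeric(volume)[mask]
  vol_ml <- length(x) * prod(spacing) / 1000
  c(
    physical_volume_ml = vol_ml,
    physical_mass_g = vol_ml * mean(x + 1000) / 1000
  )
}
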