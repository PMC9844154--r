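#' The 9 fractal features
#'
#' Box-counting descriptors of the ROI geometry and intensity landscape:
#' box-counting dimension of the mask and of its surface, a differential
#' box-counting dimension of the intensity image, gliding-box lacunarity at
#' box sizes 2, 4 and 8, and box-counting dimensions of the intensity
#' super-level sets at the 25th, 50th and 75th masked-intensity quantiles.
#' Dimensions are least-squares slopes of `log N(s)` against `log(1/s)` over
#' dyadic box sizes within the mask bounding box.
#'
#' @param volume a [voxel_volume()].
#' @param mask an [roi_mask()].
#' @return named numeric vector of 9 features (prefixed `fractal_`).
#' @export
fractal_features <- function(volume, mask) {
  check_aligned(volume, mask)
  ix <- which(unclass(mask), arr.ind = TRUE)
  lo <- apply(ix, 2, min)
  hi <- apply(ix, 2, max)
  span <- hi - lo + 1
  if (any(span < 4)) {
    stop("fractal features need an ROI spanning >= 4 voxels per axis", call. = FALSE)
  }
  sizes <- 2^(0:20)
  sizes <- sizes[sizes <= max(2, min(span) / 2)]
  ix0 <- sweep(ix, 2, lo) # 0-based within bounding box

  surf <- which(surface_voxels(mask), arr.ind = TRUE)
  surf0 <- sweep(surf, 2, lo)

  x <- as.numeric(volume)[mask]
  qs <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
  level_dim <- vapply(qs, function(q) {
    keep <- x >= q
    if (!any(keep)) return(0)
    box_dimension(ix0[keep, , drop = FALSE], sizes)
  }, numeric(1))

  c(
    fractal_mask_dimension = box_dimension(ix0, sizes),
    fractal_boundary_dimension = box_dimension(surf0, sizes),
    fractal_intensity_dimension = dbc_dimension(volume, mask, ix, lo, span, sizes),
    fractal_lacunarity_2 = lacunarity(ix0, span, 2),
    fractal_lacunarity_4 = lacunarity(ix0, span, 4),
    fractal_lacunarity_8 = lacunarity(ix0, span, 8),
    fractal_levelset_dimension_q25 = level_dim[1],
    fractal_levelset_dimension_q50 = level_dim[2],
    fractal_levelset_dimension_q75 = level_dim[3]
  )
}

box_count <- function(coords0, s) {
  if (nrow(coords0) == 0) return(0L)
  b <- coords0 %/% s
  length(unique(b[, 1] + 4096 * (b[, 2] + 4096 * b[, 3])))
}

box_dimension <- function(coords0, sizes) {
  n <- vapply(sizes, function(s) box_count(coords0, s), integer(1))
  keep <- n > 0
  if (sum(keep) < 2) return(0)
  unname(coef(lm(log(n[keep]) ~ log(1 / sizes[keep])))[2])
}

# differential box counting on the masked intensity landscape: per box of
# side s, (intensity relief) / (s * gray-per-voxel unit) + 1 columns of boxes
dbc_dimension <- function(volume, mask, ix, lo, span, sizes) {
  x <- as.numeric(volume)[mask]
  rng <- range(x)
  g <- if (diff(rng) > 0) (x - rng[1]) / diff(rng) * (min(span) - 1) else rep(0, length(x))
  ix0 <- sweep(ix, 2, lo)
  counts <- vapply(sizes, function(s) {
    key <- (ix0[, 1] %/% s) + 4096 * ((ix0[, 2] %/% s) + 4096 * (ix0[, 3] %/% s))
    mx <- tapply(g, key, max)
    mn <- tapply(g, key, min)
    sum(floor((mx - mn) / s) + 1)
  }, numeric(1))
  keep <- counts > 0
  if (sum(keep) < 2) return(0)
  unname(coef(lm(log(counts[keep]) ~ log(1 / sizes[keep])))[2])
}

# gliding-box lacunarity over the non-overlapping box partition:
# Lambda = var(mass) / mean(mass)^2 + 1, masses include empty boxes within
# the bounding box
lacunarity <- function(coords0, span, s) {
  nb <- prod(ceiling(span / s))
  key <- (coords0[, 1] %/% s) + 4096 * ((coords0[, 2] %/% s) + 4096 * (coords0[, 3] %/% s))
  mass <- tabulate(as.integer(factor(key)), nbins = length(unique(key)))
  mass <- c(mass, rep(0, nb - length(mass)))
  mu <- mean(mass)
  if (mu == 0) return(1)
  mean((mass - mu)^2) / mu^2 + 1
}
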