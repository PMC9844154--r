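#' Resample a volume and mask to isotropic spacing
#'
#' Trilinear interpolation for intensities and nearest-neighbour for the
#' mask, onto a grid with the requested spacing on every axis. When the
#' input is already isotropic at the target spacing the arrays are returned
#' unchanged. The output grid shares the input origin and spans the same
#' physical extent.
#'
#' @param volume a [voxel_volume()].
#' @param mask an [roi_mask()] aligned with `volume`.
#' @param target_spacing positive scalar, target spacing in mm (default 1).
#' @return list with elements `volume` and `mask`.
#' @export
resample_isotropic <- function(volume, mask, target_spacing = 1) {
  check_aligned(volume, mask)
  stopifnot(target_spacing > 0)
  sp <- vol_spacing(volume)
  if (all(abs(sp - target_spacing) < 1e-12)) {
    return(list(volume = volume, mask = mask))
  }
  d <- dim(volume)
  # output grid: same origin, spacing = target on all axes, same extent
  nd <- pmax(2L, as.integer(floor((d - 1) * sp / target_spacing + 1e-9)) + 1L)
  # fractional source coordinates (1-based) of each output sample per axis
  ax_coord <- lapply(1:3, function(a) {
    x <- 1 + (seq_len(nd[a]) - 1) * target_spacing / sp[a]
    pmin(pmax(x, 1), d[a])
  })
  lo <- lapply(1:3, function(a) pmin(floor(ax_coord[[a]]), d[a] - 1L))
  fr <- lapply(1:3, function(a) ax_coord[[a]] - lo[[a]])

  g <- expand.grid(i = seq_len(nd[1]), j = seq_len(nd[2]), k = seq_len(nd[3]))
  x0 <- lo[[1]][g$i]; y0 <- lo[[2]][g$j]; z0 <- lo[[3]][g$k]
  fx <- fr[[1]][g$i]; fy <- fr[[2]][g$j]; fz <- fr[[3]][g$k]
  v <- unclass(volume)
  idx <- function(dx, dy, dz) {
    cbind(x0 + dx, y0 + dy, z0 + dz)
  }
  out <- (1 - fx) * (1 - fy) * (1 - fz) * v[idx(0, 0, 0)] +
    fx * (1 - fy) * (1 - fz) * v[idx(1, 0, 0)] +
    (1 - fx) * fy * (1 - fz) * v[idx(0, 1, 0)] +
    fx * fy * (1 - fz) * v[idx(1, 1, 0)] +
    (1 - fx) * (1 - fy) * fz * v[idx(0, 0, 1)] +
    fx * (1 - fy) * fz * v[idx(1, 0, 1)] +
    (1 - fx) * fy * fz * v[idx(0, 1, 1)] +
    fx * fy * fz * v[idx(1, 1, 1)]

  # nearest neighbour for the mask
  nn <- lapply(1:3, function(a) pmin(pmax(round(ax_coord[[a]]), 1), d[a]))
  m <- unclass(mask)[cbind(nn[[1]][g$i], nn[[2]][g$j], nn[[3]][g$k])]
  if (!any(m)) stop("mask vanished after resampling (degenerate ROI)", call. = FALSE)
  list(
    volume = voxel_volume(array(out, nd),
      spacing = rep(target_spacing, 3),
      origin = attr(volume, "origin") %||% c(0, 0, 0)
    ),
    mask = roi_mask(array(m, nd))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Discretize masked intensities into integer gray levels
#'
#' Gray levels are assigned as `1 + floor((x - min) / width)` and capped at
#' `Ng`. With `method = "fixed_count"` the width is chosen so the masked
#' intensity range spans `n_bins` levels; with `method = "fixed_width"` the
#' supplied width in HU is used directly. A zero intensity range yields a
#' single level 1.
#'
#' @param volume a [voxel_volume()].
#' @param mask an [roi_mask()].
#' @param method `"fixed_count"` (default) or `"fixed_width"`.
#' @param n_bins number of bins for `"fixed_count"` (default 32).
#' @param bin_width bin width in HU for `"fixed_width"`.
#' @return object of class `discretized_roi`: list with `levels` (3D integer
#'   array, 0 outside the mask), `ng` (number of gray levels), and `binning`
#'   descriptor.
#' @export
discretize <- function(volume, mask, method = c("fixed_count", "fixed_width"),
                       n_bins = 32, bin_width = NULL) {
  check_aligned(volume, mask)
  method <- match.arg(method)
  x <- as.numeric(volume)[mask]
  rng <- range(x)
  lev <- integer(length(x))
  if (diff(rng) == 0) {
    lev[] <- 1L
    ng <- 1L
    width <- if (method == "fixed_width") bin_width else 0
  } else if (method == "fixed_count") {
    stopifnot(n_bins >= 1)
    width <- diff(rng) / n_bins
    lev <- pmin(1L + as.integer(floor((x - rng[1]) / width)), as.integer(n_bins))
    ng <- as.integer(n_bins)
  } else {
    stopifnot(!is.null(bin_width), bin_width > 0)
    width <- bin_width
    lev <- 1L + as.integer(floor((x - rng[1]) / width))
    ng <- max(lev)
  }
  arr <- array(0L, dim(mask))
  arr[mask] <- lev
  structure(
    list(
      levels = arr, ng = ng,
      binning = list(method = method, width = width, min = rng[1], max = rng[2])
    ),
    class = "discretized_roi"
  )
}
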