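#' The 14 shape features
#'
#' 3D shape descriptors of the ROI mask. The surface mesh (area and enclosed
#' volume) comes from marching tetrahedra on a lightly smoothed indicator
#' field, which removes the voxelization staircase so that rasterized
#' spheres approach sphericity 1. Diameters are maximum pairwise distances
#' among surface voxels; axis lengths derive from the principal components
#' of the physical voxel coordinates.
#'
#' @param mask an [roi_mask()].
#' @param spacing voxel spacing in mm (length 3).
#' @return named numeric vector of 14 features (prefixed `shape_`), mm-based.
#' @export
shape_features <- function(mask, spacing = c(1, 1, 1)) {
  m <- unclass(mask) * 1.0
  d <- dim(m)
  n <- sum(m)
  # pad so the iso-surface closes, smooth to suppress voxel staircase
  pd <- d + 4L
  padded <- array(0, pd)
  padded[3:(d[1] + 2), 3:(d[2] + 2), 3:(d[3] + 2)] <- m
  sm <- smooth3d(padded, sigma = 1)
  av <- march_area_volume(as.numeric(sm), pd, spacing, iso = 0.5)
  if (av[["area"]] <= 0 || av[["volume"]] <= 0) {
    # thin structures vanish under smoothing; mesh the raw indicator instead
    av <- march_area_volume(as.numeric(padded), pd, spacing, iso = 0.5)
  }
  area <- av[["area"]]
  mesh_vol <- av[["volume"]]
  vox_vol <- n * prod(spacing)
  sphericity <- (pi^(1 / 3) * (6 * mesh_vol)^(2 / 3)) / area

  # surface voxels: foreground with at least one 6-neighbour background
  surf <- surface_voxels(mask)
  coords <- (which(surf, arr.ind = TRUE) - 1) *
    matrix(spacing, sum(surf), 3, byrow = TRUE)
  d3 <- if (nrow(coords) > 1) max_pairwise_dist(coords) else 0
  d2 <- function(plane_axis) {
    # maximum in-plane diameter over all planes orthogonal to plane_axis
    ix <- which(surf, arr.ind = TRUE)
    planes <- split.data.frame(ix, ix[, plane_axis])
    best <- 0
    for (pl in planes) {
      cc <- (pl - 1) * matrix(spacing, nrow(pl), 3, byrow = TRUE)
      if (nrow(cc) > 1) best <- max(best, max_pairwise_dist(as.matrix(cc)))
    }
    best
  }
  all_coords <- (which(unclass(mask), arr.ind = TRUE) - 1) *
    matrix(spacing, n, 3, byrow = TRUE)
  if (n > 1) {
    ev <- eigen(stats::cov(all_coords) * (n - 1) / n, symmetric = TRUE,
                only.values = TRUE)$values
    ev <- pmax(ev, 0)
  } else {
    ev <- c(0, 0, 0)
  }
  axes <- 4 * sqrt(ev)
  c(
    shape_mesh_volume = mesh_vol,
    shape_voxel_volume = vox_vol,
    shape_surface_area = area,
    shape_surface_volume_ratio = area / mesh_vol,
    shape_sphericity = sphericity,
    shape_maximum_3d_diameter = d3,
    shape_maximum_2d_diameter_slice = d2(3),
    shape_maximum_2d_diameter_column = d2(2),
    shape_maximum_2d_diameter_row = d2(1),
    shape_major_axis_length = axes[1],
    shape_minor_axis_length = axes[2],
    shape_least_axis_length = axes[3],
    shape_elongation = if (ev[1] > 0) sqrt(ev[2] / ev[1]) else 1,
    shape_flatness = if (ev[1] > 0) sqrt(ev[3] / ev[1]) else 1
  )
}

surface_voxels <- function(mask) {
  m <- unclass(mask)
  d <- dim(m)
  shift <- function(arr, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) {
      idx_dst[[ax]] <- (1 + by):d[ax]
      idx_src[[ax]] <- 1:(d[ax] - by)
    } else {
      idx_dst[[ax]] <- 1:(d[ax] + by)
      idx_src[[ax]] <- (1 - by):d[ax]
    }
    out[idx_dst[[1]], idx_dst[[2]], idx_dst[[3]]] <-
      arr[idx_src[[1]], idx_src[[2]], idx_src[[3]]]
    out
  }
  interior <- m
  for (ax in 1:3) {
    for (by in c(-1, 1)) {
      interior <- interior & shift(m, ax, by)
    }
  }
  m & !interior
}
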