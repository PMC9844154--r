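#' Build the gray-level size-zone matrix (GLSZM)
#'
#' Zones are connected components of masked voxels sharing the same gray
#' level: neighbouring voxels with the same discretized intensity are grouped
#' in three dimensions (26-connectivity) or within-slice in two dimensions
#' (8-connectivity). `P[i, j]` counts zones of gray level `i` and size `j`
#' voxels; the matrix therefore satisfies `sum(P) == Nz` (zone count) and
#' `sum(j * P[, j]) == Nv` (masked voxel count).
#'
#' @param roi a `discretized_roi` from [discretize()].
#' @param connectivity `"3D-26"` (default) or `"2D-8"`.
#' @return object of class `size_zone_matrix`: list with integer matrix `P`
#'   (`ng` rows, `max zone size` columns), `nz`, `nv`, `ng`.
#' @export
build_glszm <- function(roi, connectivity = c("3D-26", "2D-8")) {
  connectivity <- match.arg(connectivity)
  lev <- roi$levels
  if (!any(lev > 0)) stop("empty ROI", call. = FALSE)
  labels <- cc_label_3d(as.integer(lev), dim(lev), connectivity == "3D-26")
  nz <- attr(labels, "n_zones")
  inside <- lev > 0
  zone_size <- tabulate(labels[inside], nbins = nz)
  # gray level of each zone: level at first voxel of each zone
  zone_level <- integer(nz)
  zone_level[labels[inside]] <- lev[inside]
  jmax <- max(zone_size)
  P <- matrix(0L, nrow = roi$ng, ncol = jmax)
  tab <- table(factor(zone_level, levels = seq_len(roi$ng)),
               factor(zone_size, levels = seq_len(jmax)))
  P[] <- as.integer(tab)
  structure(
    list(P = P, nz = nz, nv = sum(inside), ng = roi$ng,
         connectivity = connectivity),
    class = "size_zone_matrix"
  )
}

#' The 16 GLSZM texture features
#'
#' Standard size-zone statistics over the normalized matrix `p = P / Nz`. In
#' particular gray level variance `GLV = sum p(i,j) (i - mu)^2` with
#' `mu = sum i p(i,j)`, and large area low gray level emphasis
#' `LALGLE = (1/Nz) sum P(i,j) j^2 / i^2`, the two features of the published
#' predicted-TILes model.
#'
#' @param szm a `size_zone_matrix` from [build_glszm()].
#' @return named numeric vector of 16 features (prefixed `glszm_`).
#' @export
glszm_features <- function(szm) {
  P <- szm$P
  nz <- szm$nz
  if (nz < 1) stop("undefined GLSZM features: no zones", call. = FALSE)
  nv <- szm$nv
  ng <- nrow(P)
  jmax <- ncol(P)
  i <- seq_len(ng)
  j <- seq_len(jmax)
  p <- P / nz
  pg <- rowSums(P) # gray-level marginal (counts)
  pz <- colSums(P) # size marginal (counts)
  i2 <- i^2
  j2 <- j^2
  mu_i <- sum(i * rowSums(p))
  mu_j <- sum(j * colSums(p))
  pvec <- p[p > 0]
  c(
    glszm_small_area_emphasis = sum(sweep(P, 2, j2, "/")) / nz,
    glszm_large_area_emphasis = sum(sweep(P, 2, j2, "*")) / nz,
    glszm_gray_level_nonuniformity = sum(pg^2) / nz,
    glszm_gray_level_nonuniformity_normalized = sum(pg^2) / nz^2,
    glszm_size_zone_nonuniformity = sum(pz^2) / nz,
    glszm_size_zone_nonuniformity_normalized = sum(pz^2) / nz^2,
    glszm_zone_percentage = nz / nv,
    glszm_gray_level_variance = sum(rowSums(p) * (i - mu_i)^2),
    glszm_zone_variance = sum(colSums(p) * (j - mu_j)^2),
    glszm_zone_entropy = -sum(pvec * log2(pvec)),
    glszm_low_gray_level_zone_emphasis = sum(pg / i2) / nz,
    glszm_high_gray_level_zone_emphasis = sum(pg * i2) / nz,
    glszm_small_area_low_gray_level_emphasis =
      sum(outer(1 / i2, 1 / j2) * P) / nz,
    glszm_small_area_high_gray_level_emphasis =
      sum(outer(i2, 1 / j2) * P) / nz,
    glszm_large_area_low_gray_level_emphasis =
      sum(outer(1 / i2, j2) * P) / nz,
    glszm_large_area_high_gray_level_emphasis =
      sum(outer(i2, j2) * P) / nz
  )
}
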