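#' The 24 GLCM texture features
#'
#' Symmetric gray-level co-occurrence matrices are built for the 13 unique
#' distance-1 direction offsets in 3D; features are computed per direction
#' on the normalized matrix and averaged over the directions that contain at
#' least one voxel pair.
#'
#' @param roi a `discretized_roi` from [discretize()].
#' @return named numeric vector of 24 features (prefixed `glcm_`).
#' @export
glcm_features <- function(roi) {
  offs <- glcm_offsets()
  counts <- glcm_counts(as.integer(roi$levels), dim(roi$levels), offs, roi$ng)
  per_dir <- apply(counts, 3, function(m) {
    if (sum(m) == 0) return(NULL)
    glcm_features_one(m / sum(m), roi$ng)
  })
  if (is.matrix(per_dir)) {
    # all directions usable: apply() simplified to a matrix (features x dirs)
    return(rowMeans(per_dir))
  }
  keep <- !vapply(per_dir, is.null, logical(1))
  if (!any(keep)) stop("undefined GLCM features: ROI has no voxel pairs", call. = FALSE)
  rowMeans(do.call(cbind, per_dir[keep]))
}

# the 13 unique 3D direction offsets at Chebyshev distance 1
glcm_offsets <- function() {
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), ]
  # keep one of each +/- pair
  keep <- apply(g, 1, function(v) {
    nz <- which(v != 0)[1]
    v[nz] > 0
  })
  storage.mode(g) <- "integer"
  g[keep, , drop = FALSE]
}

glcm_features_one <- function(p, ng) {
  i <- seq_len(ng)
  px <- rowSums(p)
  py <- colSums(p) # equals px for symmetric p
  mux <- sum(i * px)
  muy <- sum(i * py)
  sdx <- sqrt(sum((i - mux)^2 * px))
  sdy <- sqrt(sum((i - muy)^2 * py))
  imat <- matrix(i, ng, ng)
  jmat <- t(imat)
  dif <- abs(imat - jmat)
  # difference distribution p_{x-y}(k), k = 0..ng-1
  pxy_d <- vapply(0:(ng - 1), function(k) sum(p[dif == k]), numeric(1))
  kd <- 0:(ng - 1)
  da <- sum(kd * pxy_d)
  # sum distribution p_{x+y}(k), k = 2..2 ng
  smat <- imat + jmat
  pxy_s <- vapply(2:(2 * ng), function(k) sum(p[smat == k]), numeric(1))
  ks <- 2:(2 * ng)
  pnz <- p[p > 0]
  hxy <- -sum(pnz * log2(pnz))
  eps <- .Machine$double.eps
  pxpy <- outer(px, py)
  hxy1 <- -sum(p * log2(pxpy + eps))
  hxy2 <- -sum(pxpy * log2(pxpy + eps))
  hx <- -sum(px[px > 0] * log2(px[px > 0]))
  hy <- -sum(py[py > 0] * log2(py[py > 0]))
  imc1 <- if (max(hx, hy) > 0) (hxy - hxy1) / max(hx, hy) else 0
  imc2 <- sqrt(pmax(0, 1 - exp(-2 * (hxy2 - hxy))))
  corr <- if (sdx > 0 && sdy > 0) {
    (sum(imat * jmat * p) - mux * muy) / (sdx * sdy)
  } else {
    1
  }
  c(
    glcm_autocorrelation = sum(imat * jmat * p),
    glcm_joint_average = mux,
    glcm_cluster_prominence = sum((imat + jmat - mux - muy)^4 * p),
    glcm_cluster_shade = sum((imat + jmat - mux - muy)^3 * p),
    glcm_cluster_tendency = sum((imat + jmat - mux - muy)^2 * p),
    glcm_contrast = sum((imat - jmat)^2 * p),
    glcm_correlation = corr,
    glcm_difference_average = da,
    glcm_difference_entropy = -sum(pxy_d[pxy_d > 0] * log2(pxy_d[pxy_d > 0])),
    glcm_difference_variance = sum((kd - da)^2 * pxy_d),
    glcm_inverse_difference = sum(p / (1 + dif)),
    glcm_inverse_difference_moment = sum(p / (1 + dif^2)),
    glcm_idmn = sum(p / (1 + dif^2 / ng^2)),
    glcm_idn = sum(p / (1 + dif / ng)),
    glcm_imc1 = imc1,
    glcm_imc2 = imc2,
    glcm_inverse_variance = sum(p[dif > 0] / dif[dif > 0]^2),
    glcm_joint_energy = sum(p^2),
    glcm_joint_entropy = hxy,
    glcm_mcc = glcm_mcc(p, px, py),
    glcm_maximum_probability = max(p),
    glcm_sum_average = sum(ks * pxy_s),
    glcm_sum_entropy = -sum(pxy_s[pxy_s > 0] * log2(pxy_s[pxy_s > 0])),
    glcm_sum_squares = sum((imat - mux)^2 * p)
  )
}

# maximal correlation coefficient: sqrt of second-largest eigenvalue of
# Q(i,j) = sum_k p(i,k) p(j,k) / (px(i) py(k)), over occupied gray levels
glcm_mcc <- function(p, px, py) {
  keep <- px > 0
  if (sum(keep) < 2) return(1)
  psub <- p[keep, keep, drop = FALSE]
  pxs <- px[keep]
  pys <- py[keep]
  Q <- (psub / pxs) %*% t(psub / matrix(pys, nrow(psub), ncol(psub), byrow = TRUE))
  ev <- sort(Re(eigen(Q, only.values = TRUE)$values), decreasing = TRUE)
  sqrt(pmax(0, ev[2]))
}
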