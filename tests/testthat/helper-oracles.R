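# Independent oracles and small fixtures shared across tests.

# Brute-force flood-fill zone labelling, written against the definition:
# zones are maximal sets of masked voxels with equal level connected under
# 26- (3D) or 8- (in-slice) adjacency. Plain per-voxel BFS, no shared code
# with the package implementation.
oracle_zones <- function(levels, conn26 = TRUE) {
  d <- dim(levels)
  seen <- array(FALSE, d)
  zones <- list()
  for (z in seq_len(d[3])) for (y in seq_len(d[2])) for (x in seq_len(d[1])) {
    if (levels[x, y, z] == 0 || seen[x, y, z]) next
    lev <- levels[x, y, z]
    queue <- list(c(x, y, z))
    seen[x, y, z] <- TRUE
    members <- 0
    while (length(queue)) {
      v <- queue[[1]]
      queue <- queue[-1]
      members <- members + 1
      zr <- if (conn26) (v[3] - 1):(v[3] + 1) else v[3]
      for (zz in zr) for (yy in (v[2] - 1):(v[2] + 1)) for (xx in (v[1] - 1):(v[1] + 1)) {
        if (xx < 1 || yy < 1 || zz < 1 || xx > d[1] || yy > d[2] || zz > d[3]) next
        if (seen[xx, yy, zz] || levels[xx, yy, zz] != lev) next
        seen[xx, yy, zz] <- TRUE
        queue[[length(queue) + 1]] <- c(xx, yy, zz)
      }
    }
    zones[[length(zones) + 1]] <- list(level = lev, size = members)
  }
  zones
}

# size-zone matrix from the oracle zone list
oracle_szm <- function(levels, ng, conn26 = TRUE) {
  zs <- oracle_zones(levels, conn26)
  sizes <- vapply(zs, `[[`, numeric(1), "size")
  levs <- vapply(zs, `[[`, numeric(1), "level")
  P <- matrix(0L, ng, max(sizes))
  for (k in seq_along(zs)) P[levs[k], sizes[k]] <- P[levs[k], sizes[k]] + 1L
  P
}

# the worked single-slice example: levels [[1,1,2],[1,2,2],[3,3,3]] by rows
worked_roi <- function() {
  lev <- array(0L, c(3, 3, 1))
  lev[, , 1] <- t(matrix(c(1, 1, 2, 1, 2, 2, 3, 3, 3), 3, byrow = TRUE))
  structure(list(levels = lev, ng = 3L, binning = list(method = "given")),
            class = "discretized_roi")
}

make_ball_mask <- function(radius, dim = 2 * radius + 5) {
  ctr <- (dim + 1) / 2
  g <- expand.grid(x = 1:dim, y = 1:dim, z = 1:dim)
  roi_mask(array((g$x - ctr)^2 + (g$y - ctr)^2 + (g$z - ctr)^2 <= radius^2,
                 c(dim, dim, dim)))
}

random_volume <- function(dim = c(8, 8, 8), seed = 1) {
  set.seed(seed)
  voxel_volume(array(rnorm(prod(dim), 50, 15), dim))
}

# one tiny synthetic grid table builder
grid_row <- function(id, di, ds, epi = 0.3, tme = 1) {
  tibble::tibble(
    grid_id = id, intratumoral_til_density = di, stromal_til_density = ds,
    epithelium_area = epi, tme_area = tme
  )
}
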