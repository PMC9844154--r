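test_that("first-order statistics hit closed forms on degenerate ROIs", {
  cvol <- voxel_volume(array(5, c(3, 3, 3)))
  cm <- roi_mask(array(TRUE, c(3, 3, 3)))
  roi <- discretize(cvol, cm)
  f <- first_order_features(cvol, cm, roi)
  expect_length(f, 18)
  expect_equal(f[["firstorder_mean"]], 5)
  expect_equal(f[["firstorder_median"]], 5)
  expect_equal(f[["firstorder_variance"]], 0)
  expect_equal(f[["firstorder_entropy"]], 0)
  expect_equal(f[["firstorder_uniformity"]], 1)

  # two levels, half each: uniformity 0.5, entropy 1 bit
  v2 <- voxel_volume(array(rep(c(0, 10), each = 4), c(2, 2, 2)))
  m2 <- roi_mask(array(TRUE, c(2, 2, 2)))
  r2 <- discretize(v2, m2, method = "fixed_width", bin_width = 10)
  f2 <- first_order_features(v2, m2, r2)
  expect_equal(f2[["firstorder_uniformity"]], 0.5)
  expect_equal(f2[["firstorder_entropy"]], 1)
})

test_that("shape features: single voxel volume, ball sphericity, 14 values", {
  m1 <- array(FALSE, c(5, 5, 5))
  m1[3, 3, 3] <- TRUE
  f1 <- shape_features(roi_mask(m1))
  expect_length(f1, 14)
  expect_equal(f1[["shape_voxel_volume"]], 1)
  expect_true(all(is.finite(f1)))

  fb <- shape_features(make_ball_mask(20, 45))
  expect_gte(fb[["shape_sphericity"]], 0.95)
  expect_lte(fb[["shape_sphericity"]], 1.0)
  # diameters of a radius-20 ball are close to 40 mm
  expect_equal(fb[["shape_maximum_3d_diameter"]], 40, tolerance = 0.06)
  expect_equal(fb[["shape_maximum_2d_diameter_slice"]], 40, tolerance = 0.06)
  # principal axes of a ball are equal: elongation and flatness near 1
  expect_equal(fb[["shape_elongation"]], 1, tolerance = 0.02)
  expect_equal(fb[["shape_flatness"]], 1, tolerance = 0.02)
})

test_that("CDF features match closed forms and count 5", {
  # symmetric distribution: mean equals median
  v <- voxel_volume(array(c(1, 2, 2, 3, 1, 2, 2, 3), c(2, 2, 2)))
  m <- roi_mask(array(TRUE, c(2, 2, 2)))
  f <- cdf_features(v, m)
  expect_length(f, 5)
  expect_equal(f[["cdf_mean_minus_median"]], 0)

  # uniform ramp of distinct values: AUC 0.5 within 1/n
  n <- 64
  vr <- voxel_volume(array(seq_len(n), c(4, 4, 4)))
  fr <- cdf_features(vr, roi_mask(array(TRUE, c(4, 4, 4))))
  expect_equal(fr[["cdf_auc"]], 0.5, tolerance = 1 / n)

  # zero range: degenerate conventions, flagged
  fc <- cdf_features(voxel_volume(array(3, c(2, 2, 2))), m)
  expect_equal(fc[["cdf_auc"]], 0.5)
  expect_true(attr(fc, "degenerate"))
})

test_that("physical features: volume in mL and mass proxy in g", {
  m <- roi_mask(array(TRUE, c(10, 10, 10)))
  v0 <- voxel_volume(array(0, c(10, 10, 10)))
  f <- physical_features(v0, m)
  expect_length(f, 2)
  expect_equal(f[["physical_volume_ml"]], 1.0)
  expect_equal(f[["physical_mass_g"]], 1.0) # 0 HU ~ water ~ 1 g/mL
})

test_that("fractal features: solid-cube and slab dimension limits, count 9", {
  cube <- array(FALSE, c(20, 20, 20))
  cube[3:18, 3:18, 3:18] <- TRUE
  vol <- random_volume(c(20, 20, 20), seed = 6)
  f <- fractal_features(vol, roi_mask(cube))
  expect_length(f, 9)
  expect_gte(f[["fractal_mask_dimension"]], 2.8)
  expect_lte(f[["fractal_mask_dimension"]], 3.0)

  # a thin slab (minimum 4-voxel thickness): its boundary is dominated by
  # two plates, so the boundary dimension sits near the planar limit 2
  slab <- array(FALSE, c(24, 24, 6))
  slab[3:22, 3:22, 2:5] <- TRUE
  vs <- random_volume(c(24, 24, 6), seed = 7)
  fs <- fractal_features(vs, roi_mask(slab))
  expect_gte(fs[["fractal_boundary_dimension"]], 1.8)
  expect_lte(fs[["fractal_boundary_dimension"]], 2.4)
  expect_gt(fs[["fractal_mask_dimension"]], fs[["fractal_boundary_dimension"]])

  tiny <- array(FALSE, c(6, 6, 6))
  tiny[2:4, 2:4, 2:3] <- TRUE
  expect_error(fractal_features(random_volume(c(6, 6, 6)), roi_mask(tiny)),
               ">= 4 voxels")
})

test_that("the extractor returns 88 finite named features in 7 fixed categories", {
  cfg <- sim_config()
  vm <- simulate_tumor_volume(0.5, cfg, seed = 21)
  fv <- extract_features(vm$volume, vm$mask)
  expect_equal(ncol(fv), 88)
  expect_true(all(is.finite(unlist(fv))))
  cat_tab <- feature_catalog()
  expect_equal(names(fv), cat_tab$feature)
  counts <- table(cat_tab$category)
  expect_equal(unname(counts[c("first_order", "shape", "glcm", "glszm",
                               "cdf", "physical", "fractal")]),
               c(18, 14, 24, 16, 5, 2, 9), ignore_attr = TRUE)
})

test_that("features are invariant to translating the ROI within the volume", {
  vm <- simulate_tumor_volume(0.6, sim_config(volume_shape = c(20, 20, 20),
                                              mask_radius_range = c(5, 6)),
                              seed = 3)
  pad <- function(a, off, newd) {
    out <- array(0, newd)
    out[off[1] + seq_len(dim(a)[1]), off[2] + seq_len(dim(a)[2]),
        off[3] + seq_len(dim(a)[3])] <- a
    out
  }
  d2 <- c(28, 28, 28)
  v1 <- voxel_volume(pad(unclass(vm$volume), c(0, 0, 0), d2))
  m1 <- roi_mask(pad(unclass(vm$mask) * 1, c(0, 0, 0), d2) > 0)
  v2 <- voxel_volume(pad(unclass(vm$volume), c(5, 3, 7), d2))
  m2 <- roi_mask(pad(unclass(vm$mask) * 1, c(5, 3, 7), d2) > 0)
  expect_equal(extract_features(v2, m2), extract_features(v1, m1),
               tolerance = 1e-10)
})
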