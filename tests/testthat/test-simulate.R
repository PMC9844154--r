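cfg0 <- sim_config()

test_that("masked intensity variance rises from h = 0 to h = 1 at fixed seed", {
  # texture channel alone: strictly monotone at any fixed seed
  cfg_tex <- sim_config(necrosis_effect = 0)
  for (s in 1:5) {
    lo <- simulate_tumor_volume(0, cfg_tex, seed = s)
    hi <- simulate_tumor_volume(1, cfg_tex, seed = s)
    expect_gt(var(as.numeric(hi$volume)[hi$mask]),
              var(as.numeric(lo$volume)[lo$mask]))
  }
  # full defaults: necrosis adds h = 0 variance, so compare in expectation
  vdiff <- vapply(1:10, function(s) {
    var(as.numeric(simulate_tumor_volume(1, cfg0, seed = s)$volume)[
      simulate_tumor_volume(1, cfg0, seed = s)$mask]) -
      var(as.numeric(simulate_tumor_volume(0, cfg0, seed = s)$volume)[
        simulate_tumor_volume(0, cfg0, seed = s)$mask])
  }, numeric(1))
  expect_gt(mean(vdiff), 0)
})

test_that("with both effects off the volume is independent of h", {
  cfg <- sim_config(texture_effect = 0, necrosis_effect = 0)
  a <- simulate_tumor_volume(0.1, cfg, seed = 9)
  b <- simulate_tumor_volume(0.9, cfg, seed = 9)
  expect_identical(unclass(a$volume), unclass(b$volume))
  expect_identical(unclass(a$mask), unclass(b$mask))
})

test_that("identical (h, cfg, seed) reproduce identical output everywhere", {
  a <- simulate_tumor_volume(0.4, cfg0, seed = 11)
  b <- simulate_tumor_volume(0.4, cfg0, seed = 11)
  expect_identical(a, b)
  g1 <- simulate_til_grid(0.4, cfg0, seed = 11)
  g2 <- simulate_til_grid(0.4, cfg0, seed = 11)
  expect_identical(g1, g2)
  o1 <- simulate_outcomes(0.4, cfg0, seed = 11)
  o2 <- simulate_outcomes(0.4, cfg0, seed = 11)
  expect_identical(o1, o2)
  c1 <- simulate_cohort(sim_config(n_subjects = 4))
  c2 <- simulate_cohort(sim_config(n_subjects = 4))
  expect_identical(c1, c2)
})

test_that("an undersized volume raises a sizing error", {
  expect_error(
    simulate_tumor_volume(0.5, sim_config(volume_shape = c(10, 10, 10)), seed = 1),
    "too small"
  )
})

test_that("latent heterogeneity drives extracted GLV upward across seeds", {
  hs <- seq(0, 1, length.out = 20)
  glv <- vapply(seq_along(hs), function(i) {
    vm <- simulate_tumor_volume(hs[i], cfg0, seed = 400 + i)
    extract_features(vm$volume, vm$mask)$glszm_gray_level_variance
  }, numeric(1))
  ct <- cor.test(hs, glv, method = "spearman", exact = FALSE)
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})

test_that("TIL grids saturate, calibrate, and respond monotonically to til_effect", {
  # enormous effect: every grid hot
  sat <- simulate_til_grid(1, sim_config(til_effect = 200), seed = 2)
  expect_equal(tiles_score(sat, min_grids = 10)$tiles, 1)

  # til_effect = 0: mean realized TILes equals plogis(a) within binomial error
  cfg <- sim_config(til_effect = 0, grids_per_sample = 40)
  p0 <- plogis(cfg$til_logit_base)
  realized <- vapply(1:200, function(i) {
    tiles_score(simulate_til_grid(runif(1), cfg, seed = i),
                weighting = "count", min_grids = 10)$tiles
  }, numeric(1))
  se <- sqrt(p0 * (1 - p0) / (200 * 40))
  expect_lt(abs(mean(realized) - p0), 4 * se)

  # larger til_effect never decreases mean TILes over matched seeds
  mean_tiles <- function(eff) {
    cfg <- sim_config(til_effect = eff)
    mean(vapply(1:60, function(i) {
      tiles_score(simulate_til_grid(0.7, cfg, seed = i), min_grids = 10)$tiles
    }, numeric(1)))
  }
  ms <- vapply(c(0, 1.5, 3, 6), mean_tiles, numeric(1))
  expect_true(all(diff(ms) >= 0))
})

test_that("outcome generation respects censoring and hazard settings", {
  cfg <- sim_config(censoring_rate = 0)
  evs <- vapply(1:50, function(i) simulate_outcomes(0.5, cfg, seed = i)$event,
                integer(1))
  expect_true(all(evs == 1))

  # log-hazard -1.5: Cox on 500 subjects recovers the slope within +/- 0.3
  cfg2 <- sim_config(log_hazard_per_tiles = -1.5, censoring_rate = 0.02)
  tiles <- runif(500)
  set.seed(77)
  tiles <- runif(500)
  recs <- purrr::map2(tiles, seq_along(tiles),
                      ~ simulate_outcomes(.x, cfg2, seed = .y)) |>
    purrr::list_rbind()
  recs$tiles <- tiles
  fit <- survival::coxph(survival::Surv(time, event) ~ tiles, data = recs)
  expect_lt(abs(unname(coef(fit)) + 1.5), 0.3)
})

test_that("null hazard: Cox CI covers HR = 1 in at least 90% of replicates", {
  cfg <- sim_config(log_hazard_per_tiles = 0, censoring_rate = 0.02)
  cover <- vapply(1:50, function(r) {
    set.seed(5000 + r)
    tiles <- runif(120)
    recs <- purrr::map2(tiles, seq_along(tiles),
                        ~ simulate_outcomes(.x, cfg, seed = r * 1000 + .y)) |>
      purrr::list_rbind()
    recs$tiles <- tiles
    ci <- summary(survival::coxph(survival::Surv(time, event) ~ tiles,
                                  data = recs))$conf.int
    ci[1, "lower .95"] <= 1 && 1 <= ci[1, "upper .95"]
  }, logical(1))
  expect_gte(mean(cover), 0.9)
})

test_that("cohort bundles are complete and written to disk coherently", {
  b <- simulate_cohort(sim_config(n_subjects = 3))
  expect_equal(nrow(b$subjects), 3)
  expect_length(b$volumes, 3)
  expect_equal(unique(b$til_grids$sample_id), b$subjects$subject_id)
  expect_true(all(b$subjects$true_tiles >= 0 & b$subjects$true_tiles <= 1))
  expect_true(all(b$subjects$time > 0))
  dir <- withr::local_tempdir()
  write_cohort(b, dir)
  expect_true(file.exists(file.path(dir, "til_grids.csv")))
  expect_true(file.exists(file.path(dir, "manifest.json")))
  vol_back <- read_volume_nifti(file.path(dir, "S001_volume.nii.gz"))
  expect_equal(unclass(vol_back), unclass(b$volumes[[1]]$volume),
               tolerance = 1e-6, ignore_attr = TRUE)
})
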