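#' Simulation configuration for synthetic paired cohorts
#'
#' Defines the generative chain used throughout the test suite: a latent
#' tumor-heterogeneity score `h` in `[0, 1]` drives (a) the intralesional
#' CT texture (Gaussian-field standard deviation rises with `h`), (b) the
#' necrotic low-attenuation volume fraction (rises with `1 - h`), (c) the
#' probability that a pathology grid is TIL-hot (inflamed or
#' immune-excluded; logit rises with `h`), and (d) exponential survival
#' whose log-hazard falls with TILes.
#'
#' @param n_subjects cohort size.
#' @param volume_shape voxel grid (length-3 integer).
#' @param spacing_mm voxel spacing (mm).
#' @param heterogeneity_range interval for latent `h` (subset of `[0, 1]`).
#' @param texture_effect HU gain of the texture standard deviation per unit
#'   `h` (on top of `texture_sd_base`).
#' @param necrosis_effect necrotic volume fraction at `h = 0` (linear in
#'   `1 - h`).
#' @param til_effect slope of `logit P(grid hot)` on `h`.
#' @param til_logit_base intercept of the same logit.
#' @param grids_per_sample pathology grids per sample.
#' @param baseline_hazard event rate per month at TILes 0.
#' @param log_hazard_per_tiles log hazard ratio per unit TILes.
#' @param censoring_rate independent exponential censoring rate per month
#'   (0 = no censoring).
#' @param texture_sd_base texture standard deviation (HU) at `h = 0`.
#' @param texture_smoothing Gaussian-field kernel width (voxels).
#' @param necrosis_depth HU drop of necrotic blobs below the base level.
#' @param base_hu mean lesion attenuation.
#' @param mask_radius_range ellipsoid semi-axis range (voxels).
#' @param intratumoral_threshold,stromal_threshold densities (cells/mm^2)
#'   defining "high" for the synthetic maps.
#' @param inflamed_share share of hot grids that are inflamed (vs
#'   immune-excluded).
#' @param seed integer master seed; subjects get independent,
#'   insertion-order-invariant substreams derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 220,
                       volume_shape = c(24, 24, 24),
                       spacing_mm = c(1, 1, 1),
                       heterogeneity_range = c(0, 1),
                       texture_effect = 10,
                       necrosis_effect = 0.18,
                       til_effect = 3,
                       til_logit_base = -1.5,
                       grids_per_sample = 40,
                       baseline_hazard = 0.33,
                       log_hazard_per_tiles = -1.3,
                       censoring_rate = 0.03,
                       texture_sd_base = 4,
                       texture_smoothing = 2,
                       necrosis_depth = 20,
                       base_hu = 60,
                       mask_radius_range = c(7, 9),
                       intratumoral_threshold = 500,
                       stromal_threshold = 500,
                       inflamed_share = 0.6,
                       seed = 1) {
  cfg <- as.list(environment())
  stopifnot(
    n_subjects >= 1, all(volume_shape >= 4), all(spacing_mm > 0),
    grids_per_sample >= 1, baseline_hazard > 0, censoring_rate >= 0,
    heterogeneity_range[1] >= 0, heterogeneity_range[2] <= 1,
    heterogeneity_range[1] <= heterogeneity_range[2],
    texture_sd_base > 0, necrosis_effect >= 0, necrosis_effect <= 1
  )
  structure(cfg, class = "sim_config")
}

# deterministic per-subject substream: depends only on (seed, subject, stage)
with_substream <- function(seed, subject, stage, code) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed((as.numeric(seed) * 48271 + subject * 16807 + stage * 7919) %%
             2147483647)
  code
}

#' Simulate one tumor volume and ROI mask
#'
#' An ellipsoidal lesion on a smooth base level, plus a smoothed Gaussian
#' random field whose standard deviation increases with `h`, plus contiguous
#' low-attenuation spherical blobs (necrosis) whose total volume fraction
#' increases as `h` decreases. Identical `(h, cfg, seed)` reproduce
#' identical output.
#'
#' @param h latent heterogeneity in `[0, 1]`.
#' @param cfg a [sim_config()].
#' @param seed integer substream seed.
#' @return list with `volume` ([voxel_volume()]) and `mask` ([roi_mask()]).
#' @export
simulate_tumor_volume <- function(h, cfg = sim_config(), seed = 1) {
  stopifnot(h >= 0, h <= 1)
  d <- cfg$volume_shape
  with_substream(seed, 0, 2, {
    radii <- runif(3, cfg$mask_radius_range[1], cfg$mask_radius_range[2])
    if (any(2 * radii + 2 > d)) {
      stop("volume too small to contain the minimal ROI", call. = FALSE)
    }
    ctr <- (d + 1) / 2
    g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]), z = seq_len(d[3]))
    inside <- ((g$x - ctr[1]) / radii[1])^2 + ((g$y - ctr[2]) / radii[2])^2 +
      ((g$z - ctr[3]) / radii[3])^2 <= 1
    mask <- array(inside, d)

    field <- smooth3d(array(rnorm(prod(d)), d), cfg$texture_smoothing)
    field <- field / sd(field)
    sd_h <- cfg$texture_sd_base + cfg$texture_effect * h
    vol <- cfg$base_hu + field * sd_h

    # candidate necrotic blobs, consumed until the (1 - h)-scaled volume
    # fraction target is met; radii also shrink with h, and blob interiors
    # sit near the low plateau (small residual texture). RNG draws do not
    # depend on h, so null-effect configs are h-invariant.
    n_cand <- 4L
    centers <- matrix(runif(3 * n_cand, -0.55, 0.55), ncol = 3)
    brad <- runif(n_cand, 2.5, 4.5) * (0.4 + 0.6 * (1 - h))
    target <- cfg$necrosis_effect * (1 - h) * sum(mask)
    placed <- 0
    for (b in seq_len(n_cand)) {
      if (placed >= target) break
      cb <- ctr + centers[b, ] * radii
      blob <- (g$x - cb[1])^2 + (g$y - cb[2])^2 + (g$z - cb[3])^2 <= brad[b]^2
      blob <- array(blob, d) & mask
      nb <- sum(blob)
      if (nb == 0) next
      vol[blob] <- cfg$base_hu - cfg$necrosis_depth + field[blob] * 0.3
      placed <- placed + nb
    }
    list(
      volume = voxel_volume(vol, spacing = cfg$spacing_mm),
      mask = roi_mask(mask)
    )
  })
}

#' Simulate one grid TIL map
#'
#' Each grid is TIL-hot with probability
#' `plogis(til_logit_base + til_effect * h)`; hot grids are inflamed (high
#' intra-tumoral density) or immune-excluded (high stromal density) in a
#' fixed share, cold grids are deserts with sub-threshold densities. Areas
#' are positive; the generating hot probability is attached as
#' `true_tiles` (the expectation of the realized area-weighted score).
#'
#' @inheritParams simulate_tumor_volume
#' @return tibble of grid records (columns of [read_til_grid_csv()]) with
#'   attribute `true_tiles`.
#' @export
simulate_til_grid <- function(h, cfg = sim_config(), seed = 1) {
  stopifnot(h >= 0, h <= 1, cfg$grids_per_sample >= 1)
  n <- cfg$grids_per_sample
  p_hot <- plogis(cfg$til_logit_base + cfg$til_effect * h)
  with_substream(seed, 0, 3, {
    hot <- rbinom(n, 1, p_hot) == 1
    inflamed <- hot & (runif(n) < cfg$inflamed_share)
    excluded <- hot & !inflamed
    thr_i <- cfg$intratumoral_threshold
    thr_s <- cfg$stromal_threshold
    di <- runif(n, 0, 0.8 * thr_i)
    ds <- runif(n, 0, 0.8 * thr_s)
    di[inflamed] <- thr_i * (1 + rgamma(sum(inflamed), shape = 2, rate = 2))
    ds[excluded] <- thr_s * (1 + rgamma(sum(excluded), shape = 2, rate = 2))
    tme <- runif(n, 0.5, 1.0)
    out <- tibble::tibble(
      grid_id = seq_len(n),
      intratumoral_til_density = di,
      stromal_til_density = ds,
      epithelium_area = tme * runif(n, 0.2, 0.5),
      tme_area = tme
    )
    attr(out, "true_tiles") <- p_hot
    out
  })
}

#' Simulate one censored survival record
#'
#' Event time is exponential with hazard
#' `baseline_hazard * exp(log_hazard_per_tiles * tiles)`; censoring is an
#' independent exponential at `censoring_rate` (none when 0). The observed
#' time is the minimum, in months.
#'
#' @param tiles TILes fraction in `[0, 1]`.
#' @inheritParams simulate_tumor_volume
#' @return 1-row tibble: `time`, `event`.
#' @export
simulate_outcomes <- function(tiles, cfg = sim_config(), seed = 1) {
  stopifnot(tiles >= 0, tiles <= 1)
  if (cfg$baseline_hazard <= 0) stop("baseline_hazard must be positive", call. = FALSE)
  with_substream(seed, 0, 4, {
    hz <- cfg$baseline_hazard * exp(cfg$log_hazard_per_tiles * tiles)
    t_event <- rexp(1, hz)
    t_cens <- if (cfg$censoring_rate > 0) rexp(1, cfg$censoring_rate) else Inf
    tibble::tibble(
      time = min(t_event, t_cens),
      event = as.integer(t_event <= t_cens)
    )
  })
}

#' Simulate a full paired cohort
#'
#' Per subject: latent `h` uniform over `heterogeneity_range`, a tumor
#' volume/mask, a grid TIL map, and a survival record whose hazard depends
#' on the generating (true) TILes. Subjects use independent substreams of
#' the master seed, so the bundle is reproducible and insertion-order
#' invariant.
#'
#' @param cfg a [sim_config()].
#' @param keep_volumes retain the voxel arrays (default TRUE; FALSE keeps
#'   the bundle light when only maps/outcomes are needed).
#' @return list of class `cohort_bundle`: `subjects` tibble (`subject_id`,
#'   `latent_h`, `true_tiles`, `tiles`, `time`, `event`), `volumes` (list of
#'   volume/mask pairs), `til_grids` (long tibble with `sample_id`).
#' @export
simulate_cohort <- function(cfg = sim_config(), keep_volumes = TRUE) {
  subs <- purrr::map(seq_len(cfg$n_subjects), function(i) {
    sseed <- cfg$seed * 1000 + i
    h <- with_substream(sseed, 0, 1,
      runif(1, cfg$heterogeneity_range[1], cfg$heterogeneity_range[2]))
    vm <- simulate_tumor_volume(h, cfg, seed = sseed)
    grid <- simulate_til_grid(h, cfg, seed = sseed)
    true_tiles <- attr(grid, "true_tiles")
    grid$sample_id <- sprintf("S%03d", i)
    realized <- tiles_score(grid,
      intratumoral_threshold = cfg$intratumoral_threshold,
      stromal_threshold = cfg$stromal_threshold,
      min_grids = min(10, cfg$grids_per_sample)
    )
    outcome <- simulate_outcomes(true_tiles, cfg, seed = sseed)
    list(
      row = tibble::tibble(
        subject_id = sprintf("S%03d", i), latent_h = h,
        true_tiles = true_tiles, tiles = realized$tiles,
        time = outcome$time, event = outcome$event
      ),
      vm = if (keep_volumes) vm else NULL,
      grid = grid
    )
  })
  structure(
    list(
      subjects = purrr::list_rbind(purrr::map(subs, "row")),
      volumes = if (keep_volumes) purrr::map(subs, "vm") else NULL,
      til_grids = purrr::list_rbind(purrr::map(subs, "grid")),
      config = cfg
    ),
    class = "cohort_bundle"
  )
}

#' Extract features for every subject of a cohort bundle
#'
#' @param bundle a `cohort_bundle` with volumes.
#' @param config an [extract_config()].
#' @return tibble: `sample_id` plus the 88 feature columns.
#' @export
extract_cohort_features <- function(bundle, config = extract_config()) {
  stopifnot(!is.null(bundle$volumes))
  purrr::map2(bundle$volumes, bundle$subjects$subject_id, function(vm, id) {
    dplyr::bind_cols(tibble::tibble(sample_id = id),
                     extract_features(vm$volume, vm$mask, config))
  }) |>
    purrr::list_rbind()
}

#' Write a cohort bundle to disk
#'
#' Volumes and masks as NIfTI, grid maps and outcomes as CSV, and a JSON
#' manifest of the true latent parameters.
#'
#' @param bundle a `cohort_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$volumes)) {
    for (i in seq_along(bundle$volumes)) {
      id <- bundle$subjects$subject_id[i]
      write_volume_nifti(bundle$volumes[[i]]$volume,
                         file.path(dir, paste0(id, "_volume.nii.gz")))
      write_volume_nifti(
        voxel_volume(unclass(bundle$volumes[[i]]$mask) * 1.0,
                     spacing = vol_spacing(bundle$volumes[[i]]$volume)),
        file.path(dir, paste0(id, "_mask.nii.gz"))
      )
    }
  }
  write_til_grid_csv(bundle$til_grids, file.path(dir, "til_grids.csv"))
  utils::write.csv(bundle$subjects, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config = unclass(bundle$config),
         true_parameters = bundle$subjects[, c("subject_id", "latent_h", "true_tiles")]),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}
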