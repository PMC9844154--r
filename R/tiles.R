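#' Classify grid immune phenotypes
#'
#' Each 1 mm^2 pathology grid is labelled by its TIL densities: `inflamed`
#' if the intra-tumoral TIL density reaches `intratumoral_threshold`
#' (inclusive), otherwise `immune_excluded` if the stromal TIL density
#' reaches `stromal_threshold` (inclusive), otherwise `desert`. A grid with
#' no analyzable tumor-microenvironment area is `non_evaluable`. When both
#' densities exceed their thresholds, inflamed wins: intra-tumoral
#' infiltration subsumes stromal (a convention; the underlying assay does
#' not publish its rule).
#'
#' @param grids data frame with columns `intratumoral_til_density`,
#'   `stromal_til_density`, `tme_area` (one row per grid).
#' @param intratumoral_threshold,stromal_threshold positive densities
#'   (cells per mm^2) defining "high".
#' @return the input tibble with a `phenotype` column added.
#' @export
classify_grids <- function(grids, intratumoral_threshold = 500,
                           stromal_threshold = 500) {
  stopifnot(intratumoral_threshold > 0, stromal_threshold > 0)
  if (any(grids$intratumoral_til_density < 0 | grids$stromal_til_density < 0)) {
    stop("TIL densities must be non-negative", call. = FALSE)
  }
  if (any(grids$tme_area < 0 | grids$epithelium_area %||% 0 < 0)) {
    stop("areas must be non-negative", call. = FALSE)
  }
  dplyr::mutate(
    tibble::as_tibble(grids),
    phenotype = dplyr::case_when(
      .data$tme_area == 0 ~ "non_evaluable",
      .data$intratumoral_til_density >= intratumoral_threshold ~ "inflamed",
      .data$stromal_til_density >= stromal_threshold ~ "immune_excluded",
      TRUE ~ "desert"
    )
  )
}

#' Sample-level quality control for grid TIL maps
#'
#' A sample fails QC when its total cancer-epithelium area is less than
#' `min_epithelium_mm2` or it has fewer than `min_grids` evaluable grids;
#' both bounds are strict, so a sample at exactly 0.5 mm^2 and exactly ten
#' grids passes.
#'
#' @param grids data frame of one sample's grids (columns `epithelium_area`,
#'   `tme_area`).
#' @param min_epithelium_mm2 minimum total epithelium area (default 0.5).
#' @param min_grids minimum evaluable grid count (default 10).
#' @return list with `pass` (flag) and `reason` (character, `NA` if passing).
#' @export
qc_sample <- function(grids, min_epithelium_mm2 = 0.5, min_grids = 10) {
  total_epi <- sum(grids$epithelium_area)
  n_eval <- sum(grids$tme_area > 0)
  if (total_epi < min_epithelium_mm2) {
    return(list(pass = FALSE, reason = sprintf(
      "less than %.2f mm^2 cancer epithelium (%.3f)", min_epithelium_mm2, total_epi
    )))
  }
  if (n_eval < min_grids) {
    return(list(pass = FALSE, reason = sprintf(
      "fewer than %d grids (%d evaluable)", min_grids, n_eval
    )))
  }
  list(pass = TRUE, reason = NA_character_)
}

#' TIL enrichment score (TILes)
#'
#' TILes is the fraction of the analyzable tumor-microenvironment (TME) area
#' occupied by grids with high intra-tumoral (inflamed) or high stromal
#' (immune-excluded) TIL density: the summed `tme_area` of inflamed plus
#' immune-excluded grids divided by the summed `tme_area` of all evaluable
#' grids. A grid-count mode (`weighting = "count"`) treats every evaluable
#' grid equally instead; area weighting is the default because the score
#' definition divides by the whole analyzable TME area.
#'
#' @param grids data frame of one sample's grids (columns as in
#'   [classify_grids()], plus `sample_id` optionally).
#' @param intratumoral_threshold,stromal_threshold densities defining
#'   "high", passed to [classify_grids()].
#' @param weighting `"area"` (default) or `"count"`.
#' @param qc apply [qc_sample()] first (default TRUE).
#' @param ... passed to [qc_sample()].
#' @return a 1-row tibble: `sample_id`, `tiles`, `n_grids_evaluable`,
#'   `qc_pass`, `qc_reason`. `tiles` is `NA` when QC fails.
#' @export
tiles_score <- function(grids, intratumoral_threshold = 500,
                        stromal_threshold = 500,
                        weighting = c("area", "count"), qc = TRUE, ...) {
  weighting <- match.arg(weighting)
  sample_id <- if ("sample_id" %in% names(grids)) grids$sample_id[1] else NA_character_
  if (anyDuplicated(grids$grid_id %||% seq_len(nrow(grids)))) {
    stop("grid_ids must be unique within a sample", call. = FALSE)
  }
  qcres <- if (qc) qc_sample(grids, ...) else list(pass = TRUE, reason = NA_character_)
  g <- classify_grids(grids, intratumoral_threshold, stromal_threshold)
  evaluable <- g$phenotype != "non_evaluable"
  out <- tibble::tibble(
    sample_id = sample_id,
    tiles = NA_real_,
    n_grids_evaluable = sum(evaluable),
    qc_pass = qcres$pass,
    qc_reason = qcres$reason
  )
  if (!qcres$pass) return(out)
  hot <- g$phenotype %in% c("inflamed", "immune_excluded")
  if (weighting == "area") {
    denom <- sum(g$tme_area[evaluable])
    if (denom == 0) stop("zero total analyzable TME area: TILes undefined", call. = FALSE)
    out$tiles <- sum(g$tme_area[hot]) / denom
  } else {
    if (!any(evaluable)) stop("no evaluable grids: TILes undefined", call. = FALSE)
    out$tiles <- sum(hot) / sum(evaluable)
  }
  out
}

#' Score every sample in a cohort grid table
#'
#' @param grid_table data frame of grids for many samples (must contain
#'   `sample_id`).
#' @param ... passed to [tiles_score()].
#' @return tibble with one row per sample.
#' @export
tiles_score_cohort <- function(grid_table, ...) {
  grid_table |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::group_split() |>
    purrr::map(tiles_score, ...) |>
    purrr::list_rbind()
}

#' Read / write grid TIL maps as CSV
#'
#' Columns: `sample_id`, `grid_id`, `intratumoral_til_density`,
#' `stromal_til_density`, `epithelium_area`, `tme_area`.
#'
#' @param path CSV path.
#' @return tibble of grid records.
#' @export
read_til_grid_csv <- function(path) {
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}

#' @param grid_table grid records as from [read_til_grid_csv()].
#' @rdname read_til_grid_csv
#' @export
write_til_grid_csv <- function(grid_table, path) {
  utils::write.csv(grid_table, path, row.names = FALSE)
  invisible(path)
}
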