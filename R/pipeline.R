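#' Run the full feature-selection pipeline
#'
#' The four-stage procedure that produced the published predicted-TILes
#' model: (1) median-split t-test filter of every feature against the
#' response at `alpha = 0.005` (strict); (2) removal of aliased (linearly
#' dependent) features; (3) iterative variance-inflation-factor filter at
#' cutoff 10 (strict "more than"); (4) LASSO with cross-validated penalty,
#' keeping features with non-zero coefficients. Every feature ends in
#' exactly one terminal stage recorded in the filter report.
#'
#' @param x data frame of features (samples x named features), complete
#'   cases only.
#' @param y numeric response (TILes), same length as `nrow(x)`.
#' @param alpha_t t-filter cutoff (default 0.005).
#' @param vif_cutoff VIF cutoff (default 10).
#' @param seed seed for the CV fold assignment.
#' @param lasso_rule `"min"` (default) or `"1se"`.
#' @param cv_folds CV folds for the LASSO penalty (default 10).
#' @return list of class `tiles_selection`: `model` (a `lasso_model`, or
#'   `NULL` when no feature survives), `report` (tibble: `feature`, `stage`,
#'   `t`, `p`, `coefficient`), `spearman_rho` of fitted predictions vs `y`.
#' @export
run_selection_pipeline <- function(x, y, alpha_t = 0.005, vif_cutoff = 10,
                                   seed = 1, lasso_rule = "min",
                                   cv_folds = 10) {
  x <- as.data.frame(x)
  stopifnot(all(complete.cases(x)), !anyNA(y), nrow(x) == length(y))
  report <- ttest_filter(x, y, alpha = alpha_t)
  kept <- report$feature[report$retained]
  stage <- setNames(report$stage, report$feature)

  x2 <- x[, kept, drop = FALSE]
  if (ncol(x2) > 0) {
    x3 <- drop_aliased(x2)
    stage[attr(x3, "dropped")] <- "alias"
    x4 <- vif_filter(x3, cutoff = vif_cutoff)
    stage[names(attr(x4, "dropped"))] <- "vif"
  } else {
    x4 <- x2
  }

  model <- NULL
  rho <- NA_real_
  if (ncol(x4) >= 1) {
    model <- lasso_fit(x4, y, cv_folds = min(cv_folds, nrow(x4)),
                       seed = seed, rule = lasso_rule)
    nz <- model$coefficients != 0
    stage[names(model$coefficients)[!nz]] <- "lasso_zero"
    stage[names(model$coefficients)[nz]] <- "kept"
    pred <- predict(model, x4)
    rho <- if (sd(pred) > 0 && sd(y) > 0) {
      cor(pred, y, method = "spearman")
    } else NA_real_
  }
  coefs <- if (!is.null(model)) model$coefficients else numeric(0)
  report$stage <- unname(stage[report$feature])
  report$coefficient <- unname(coefs[report$feature])
  structure(
    list(model = model, report = report, spearman_rho = rho,
         selected = report$feature[report$stage == "kept"]),
    class = "tiles_selection"
  )
}

#' @export
print.tiles_selection <- function(x, ...) {
  cat("TILes feature-selection pipeline\n")
  print(table(x$report$stage))
  if (!is.null(x$model)) {
    cat(sprintf("Spearman rho (fitted vs response): %.3f\n", x$spearman_rho))
  } else {
    cat("no features survived selection (empty model)\n")
  }
  invisible(x)
}

#' The published two-feature predicted-TILes model
#'
#' Loads the versioned model asset: gray level variance (GLSZM) with
#' coefficient 1.71e-3 and large area low gray level emphasis (GLSZM) with
#' coefficient -2.48e-5, intercept unknown (scores are defined up to an
#' additive constant).
#'
#' @return a `lasso_model`.
#' @export
published_model <- function() {
  path <- system.file("extdata", "published_model.json", package = "radtiles")
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      coefficients = unlist(spec$coefficients),
      intercept = 0, intercept_known = isTRUE(spec$intercept_known),
      lambda = NA_real_, alpha = 1,
      standardization = NULL, kkt_residual = NA_real_,
      n = NA_integer_, p = length(spec$coefficients),
      version = spec$version
    ),
    class = "lasso_model"
  )
}

#' Serialize a LASSO model to/from JSON
#'
#' @param model a `lasso_model`.
#' @param path JSON path.
#' @return `read_model_json()` returns a `lasso_model`.
#' @export
write_model_json <- function(model, path) {
  jsonlite::write_json(
    list(
      coefficients = as.list(model$coefficients),
      intercept = model$intercept, intercept_known = model$intercept_known,
      lambda = model$lambda, alpha = model$alpha,
      standardization = model$standardization,
      kkt_residual = model$kkt_residual, n = model$n, p = model$p
    ),
    path, auto_unbox = TRUE, digits = NA, null = "null"
  )
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(
    list(
      coefficients = unlist(spec$coefficients),
      intercept = spec$intercept %||% 0,
      intercept_known = isTRUE(spec$intercept_known),
      lambda = spec$lambda %||% NA_real_, alpha = spec$alpha %||% 1,
      standardization = spec$standardization,
      kkt_residual = spec$kkt_residual %||% NA_real_,
      n = spec$n %||% NA_integer_, p = length(spec$coefficients)
    ),
    class = "lasso_model"
  )
}

#' Predicted TILes for a cohort
#'
#' Scores every sample with a (fitted or published) model and assigns
#' high/low groups by the cohort median of the scores, ties going to the
#' high group — the same rule used for features during selection.
#'
#' @param features data frame of per-sample feature values; a `sample_id`
#'   column is carried through if present.
#' @param model a `lasso_model` (default: the published two-feature model).
#' @return tibble: `sample_id`, `score`, `group` (`"high"`/`"low"`).
#' @export
predict_tiles <- function(features, model = published_model()) {
  score <- predict(model, features)
  tibble::tibble(
    sample_id = features$sample_id %||% seq_along(score),
    score = score,
    group = as.character(median_split(score))
  )
}
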