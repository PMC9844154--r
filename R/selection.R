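#' Median split into high/low groups
#'
#' Samples at or above the median go to the high group; values exactly at
#' the median are classified high. With an all-equal input every sample is
#' high and the result carries a `degenerate` attribute.
#'
#' @param values numeric vector (length >= 2).
#' @return character vector `"high"`/`"low"`, with attribute `degenerate`.
#' @export
median_split <- function(values) {
  stopifnot(length(values) >= 2)
  med <- median(values)
  grp <- ifelse(values >= med, "high", "low")
  attr(grp, "degenerate") <- all(grp == "high")
  grp
}

#' t-test filter of features against TILes
#'
#' For each feature the cohort is median-split into feature-high and
#' feature-low groups (ties to high) and the response is compared between
#' the groups with a two-sample t test (pooled-variance Student form by
#' default, Welch behind `var_equal = FALSE`). Features are retained when
#' `p < alpha` strictly.
#'
#' @param x data frame / matrix of features (samples x features).
#' @param y numeric response (TILes per sample).
#' @param alpha retention cutoff (default 0.005, strict).
#' @param var_equal pooled-variance Student t (default TRUE).
#' @return tibble (one row per feature): `feature`, `t`, `p`, `retained`,
#'   `stage` (`"kept"` or `"t_filter"`), `note`.
#' @export
ttest_filter <- function(x, y, alpha = 0.005, var_equal = TRUE) {
  x <- as.data.frame(x)
  stopifnot(nrow(x) == length(y))
  res <- purrr::map(names(x), function(f) {
    grp <- median_split(x[[f]])
    hi <- y[grp == "high"]
    lo <- y[grp == "low"]
    if (length(hi) < 2 || length(lo) < 2) {
      return(tibble::tibble(
        feature = f, t = NA_real_, p = NA_real_, retained = FALSE,
        stage = "t_filter", note = "degenerate median split"
      ))
    }
    tt <- stats::t.test(hi, lo, var.equal = var_equal)
    tibble::tibble(
      feature = f, t = unname(tt$statistic), p = tt$p.value,
      retained = tt$p.value < alpha,
      stage = ifelse(tt$p.value < alpha, "kept", "t_filter"),
      note = NA_character_
    )
  })
  purrr::list_rbind(res)
}

#' Drop aliased (linearly dependent) features
#'
#' Removes columns that are linear combinations of earlier columns
#' (including the intercept), keeping the first of each dependent set. The
#' rank-revealing pass uses a QR decomposition at relative tolerance 1e-8.
#'
#' @param x data frame / matrix of features.
#' @param tol relative rank tolerance.
#' @return character vector of dropped feature names (attribute of the
#'   returned tibble), as a tibble of the retained columns.
#' @export
drop_aliased <- function(x, tol = 1e-8) {
  xm <- scale(as.matrix(x)) # center+scale so tolerance is relative
  xm[is.nan(xm)] <- 0 # constant columns: aliased with the intercept
  keep <- logical(ncol(xm))
  basis <- NULL
  for (j in seq_len(ncol(xm))) {
    cand <- cbind(basis, xm[, j])
    if (qr(cand, tol = tol)$rank == ncol(cand)) {
      keep[j] <- TRUE
      basis <- cand
    }
  }
  out <- tibble::as_tibble(as.data.frame(x)[, keep, drop = FALSE])
  attr(out, "dropped") <- names(as.data.frame(x))[!keep]
  out
}

#' Iterative variance-inflation-factor filter
#'
#' Repeatedly removes the feature with the largest VIF while the maximum
#' VIF exceeds the cutoff (strictly: a VIF of exactly 10 is kept).
#' `VIF_j = 1 / (1 - R^2_j)` from regressing feature j on the remaining
#' features. `iterative = FALSE` removes all features above the cutoff in
#' one pass instead.
#'
#' @param x data frame / matrix of alias-free features.
#' @param cutoff VIF threshold (default 10, strict "more than").
#' @param iterative worst-first removal (default TRUE).
#' @return tibble of retained columns with attribute `dropped` (named
#'   numeric of removal-time VIFs, in removal order).
#' @export
vif_filter <- function(x, cutoff = 10, iterative = TRUE) {
  x <- as.data.frame(x)
  dropped <- numeric(0)
  if (ncol(x) < 2) {
    out <- tibble::as_tibble(x)
    attr(out, "dropped") <- dropped
    return(out)
  }
  repeat {
    v <- vif_values(x)
    over <- v > cutoff
    if (!any(over, na.rm = TRUE) || ncol(x) < 2) break
    if (iterative) {
      worst <- names(which.max(v))
      dropped[worst] <- v[worst]
      x[[worst]] <- NULL
    } else {
      dropped <- c(dropped, v[over])
      x <- x[, !over, drop = FALSE]
      break
    }
  }
  out <- tibble::as_tibble(x)
  attr(out, "dropped") <- dropped
  out
}

#' @rdname vif_filter
#' @export
vif_values <- function(x) {
  xm <- as.matrix(as.data.frame(x))
  vapply(seq_len(ncol(xm)), function(j) {
    fit <- stats::lm.fit(cbind(1, xm[, -j, drop = FALSE]), xm[, j])
    tss <- sum((xm[, j] - mean(xm[, j]))^2)
    rss <- sum(fit$residuals^2)
    if (tss == 0) return(NA_real_)
    r2 <- 1 - rss / tss
    1 / max(1 - r2, .Machine$double.eps)
  }, numeric(1)) |> setNames(colnames(xm))
}
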