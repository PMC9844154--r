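#' Kaplan-Meier estimate by group
#'
#' Product-limit survival curves per group with Greenwood-based confidence
#' intervals on the log-log scale; the median is the earliest time at which
#' the curve drops to 0.5 or below (reported as `NA` = not reached when the
#' curve never does).
#'
#' @param data data frame with survival columns.
#' @param time,event,group column names (strings): follow-up time (months),
#'   event indicator (1 = progression/death), grouping variable (`NULL` for
#'   a single curve).
#' @param conf_type CI transform, `"log-log"` (default) or
#'   `"brookmeyer-crowley"` (plain linear on S).
#' @return object of class `km_fit`: list with `survfit` (the fitted
#'   curves), `medians` (tibble: group, median, CI), `n_groups`.
#' @export
km_estimate <- function(data, time = "time", event = "event", group = NULL,
                        conf_type = c("log-log", "brookmeyer-crowley")) {
  conf_type <- match.arg(conf_type)
  ct <- if (conf_type == "log-log") "log-log" else "plain"
  if (sum(data[[event]]) < 1) warning("no events in the data")
  rhs <- if (is.null(group)) "1" else group
  f <- stats::as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ", rhs))
  fit <- survival::survfit(f, data = data, conf.type = ct)
  tab <- summary(fit)$table
  if (is.null(dim(tab))) tab <- matrix(tab, 1, dimnames = list("all", names(tab)))
  # median: earliest time with S(t) <= 0.5 (not reached -> NA); CI bounds are
  # the corresponding crossing times of the Greenwood confidence curves
  grp_idx <- if (is.null(fit$strata)) {
    rep(1L, length(fit$time))
  } else {
    rep(seq_along(fit$strata), fit$strata)
  }
  cross <- function(i, values) {
    hit <- which(grp_idx == i & values <= 0.5)
    if (length(hit)) fit$time[hit[1]] else NA_real_
  }
  medians <- tibble::tibble(
    group = sub(".*=", "", rownames(tab)),
    n = tab[, "records"],
    events = tab[, "events"],
    median = vapply(seq_len(nrow(tab)), cross, numeric(1), values = fit$surv),
    ci_lower = vapply(seq_len(nrow(tab)), cross, numeric(1), values = fit$lower),
    ci_upper = vapply(seq_len(nrow(tab)), cross, numeric(1), values = fit$upper)
  )
  structure(list(survfit = fit, medians = medians,
                 n_groups = nrow(medians), data = data,
                 time = time, event = event, group = group),
            class = "km_fit")
}

#' @export
print.km_fit <- function(x, ...) {
  cat("Kaplan-Meier estimate\n")
  print(x$medians)
  invisible(x)
}

#' @rdname km_estimate
#' @param x a `km_fit`.
#' @param ... unused.
#' @return `tidy.km_fit()`: tibble of step-function points (`group`, `time`,
#'   `estimate`, `conf.low`, `conf.high`, `n.risk`, `n.event`).
#' @export
tidy.km_fit <- function(x, ...) {
  s <- x$survfit
  grp <- if (is.null(s$strata)) {
    rep("all", length(s$time))
  } else {
    rep(sub(".*=", "", names(s$strata)), s$strata)
  }
  tibble::tibble(
    group = grp, time = s$time, estimate = s$surv,
    conf.low = s$lower, conf.high = s$upper,
    n.risk = s$n.risk, n.event = s$n.event
  )
}

#' Two-group log-rank test
#'
#' @param data data frame; `time`, `event`, `group` column names.
#' @inheritParams km_estimate
#' @return tibble: `statistic` (chi-square, 1 df), `p`.
#' @export
logrank_test <- function(data, time = "time", event = "event", group = "group") {
  groups <- unique(data[[group]])
  if (length(groups) != 2) stop("log-rank test needs exactly 2 groups", call. = FALSE)
  if (sum(data[[event]]) < 1) stop("log-rank test needs at least one event", call. = FALSE)
  f <- stats::as.formula(paste0("survival::Surv(", time, ", ", event, ") ~ ", group))
  sd_ <- survival::survdiff(f, data = data)
  tibble::tibble(
    statistic = sd_$chisq,
    p = pchisq(sd_$chisq, df = 1, lower.tail = FALSE)
  )
}

#' Cox proportional hazards fits, univariate and multivariate
#'
#' Univariate mode fits one Cox model per covariate (Efron tie handling by
#' default) and reports the Wald hazard ratio, 95% CI and p per term.
#' Multivariate mode first runs all univariate fits and then fits a joint
#' model on the covariates with any univariate term p < 0.05 (strict entry
#' rule). Monotone-likelihood fits (perfect separation) are flagged by
#' infinite CI bounds.
#'
#' @param data data frame with `time`, `event` and covariate columns.
#' @param covariates character vector of covariate column names.
#' @param mode `"univariate"` or `"multivariate"`.
#' @param ties `"efron"` (default) or `"breslow"`.
#' @inheritParams km_estimate
#' @return tibble: `analysis`, `covariate`, `term`, `estimate` (log HR),
#'   `hr`, `ci_lower`, `ci_upper`, `p`, `entered` (multivariate only).
#' @export
cox_fit <- function(data, covariates, mode = c("univariate", "multivariate"),
                    time = "time", event = "event", ties = "efron") {
  mode <- match.arg(mode)
  surv <- paste0("survival::Surv(", time, ", ", event, ")")
  one <- function(covs, label) {
    f <- stats::as.formula(paste(surv, "~", paste(covs, collapse = " + ")))
    fit <- survival::coxph(f, data = data, ties = ties)
    if (sum(data[[event]]) < length(coef(fit))) {
      stop("fewer events than fitted coefficients", call. = FALSE)
    }
    s <- summary(fit)
    ci <- s$conf.int
    tibble::tibble(
      analysis = label,
      covariate = covariate_of_term(rownames(s$coefficients), covs),
      term = rownames(s$coefficients),
      estimate = s$coefficients[, "coef"],
      hr = s$coefficients[, "exp(coef)"],
      ci_lower = ci[, "lower .95"],
      ci_upper = ci[, "upper .95"],
      p = s$coefficients[, "Pr(>|z|)"]
    )
  }
  uni <- purrr::map(covariates, function(cv) one(cv, "univariate")) |>
    purrr::list_rbind()
  if (mode == "univariate") return(uni)
  sig <- uni |>
    dplyr::group_by(.data$covariate) |>
    dplyr::summarise(enter = any(.data$p < 0.05)) |>
    dplyr::filter(.data$enter) |>
    dplyr::pull(.data$covariate)
  uni$entered <- uni$covariate %in% sig
  if (!length(sig)) {
    return(dplyr::bind_rows(uni))
  }
  multi <- one(sig, "multivariate")
  multi$entered <- TRUE
  dplyr::bind_rows(uni, multi)
}

covariate_of_term <- function(terms, covs) {
  vapply(terms, function(tm) {
    hit <- covs[startsWith(tm, covs)]
    if (length(hit)) hit[which.max(nchar(hit))] else tm
  }, character(1), USE.NAMES = FALSE)
}

#' Rank and count statistics
#'
#' The remaining statistical layer: Spearman's rank correlation for
#' continuous pairs, the Wilcoxon rank-sum test for two-group comparisons
#' of continuous values, and Fisher's exact test with odds ratio for 2x2
#' tables (conditional MLE, with the sample OR alongside). All tests are
#' two-sided.
#'
#' @param x,y numeric vectors (Spearman: paired; Wilcoxon: two groups), or
#'   `table` a 2x2 integer matrix for Fisher's test.
#' @return tibbles of estimates and p values.
#' @name rank_and_count_stats
NULL

#' @rdname rank_and_count_stats
#' @export
spearman_cor <- function(x, y) {
  if (sd(x) == 0 || sd(y) == 0) {
    return(tibble::tibble(rho = NA_real_, p = NA_real_, undefined = TRUE))
  }
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  tibble::tibble(rho = unname(ct$estimate), p = ct$p.value, undefined = FALSE)
}

#' @rdname rank_and_count_stats
#' @export
wilcoxon_rank_sum <- function(x, y) {
  wt <- suppressWarnings(wilcox.test(x, y))
  tibble::tibble(statistic = unname(wt$statistic), p = wt$p.value)
}

#' @rdname rank_and_count_stats
#' @param table 2x2 matrix of non-negative integer counts.
#' @export
fisher_or <- function(table) {
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  ft <- fisher.test(table)
  a <- table[1, 1]; b <- table[1, 2]; c_ <- table[2, 1]; d <- table[2, 2]
  sample_or <- (a * d) / (b * c_) # Inf / NaN flag degenerate margins
  tibble::tibble(
    p = ft$p.value, or_conditional_mle = unname(ft$estimate),
    or_sample = sample_or,
    ci_lower = ft$conf.int[1], ci_upper = ft$conf.int[2]
  )
}

#' Predicted-TILes by best response
#'
#' Wilcoxon rank-sum comparisons of the predicted-TILes score between
#' best-response categories: responders vs progressive disease and stable
#' disease vs progressive disease.
#'
#' @param predicted data frame from [predict_tiles()] (column `score`).
#' @param best_response character vector per subject:
#'   `"responder"`, `"stable"`, `"progressive"`.
#' @return tibble with one row per comparison (`comparison`, `n1`, `n2`,
#'   `p`, `skipped`).
#' @export
response_comparison <- function(predicted, best_response) {
  stopifnot(nrow(predicted) == length(best_response))
  score <- predicted$score
  cmp <- function(a, b) {
    sa <- score[best_response == a]
    sb <- score[best_response == b]
    if (length(sa) < 2 || length(sb) < 2) {
      return(tibble::tibble(
        comparison = paste(a, "vs", b), n1 = length(sa), n2 = length(sb),
        p = NA_real_, skipped = TRUE
      ))
    }
    tibble::tibble(
      comparison = paste(a, "vs", b), n1 = length(sa), n2 = length(sb),
      p = wilcoxon_rank_sum(sa, sb)$p, skipped = FALSE
    )
  }
  dplyr::bind_rows(
    cmp("responder", "progressive"),
    cmp("stable", "progressive")
  )
}
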