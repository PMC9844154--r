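#' Kaplan-Meier curve plot
#'
#' Step curves per group with censoring ticks, from a [km_estimate()] fit.
#'
#' @param object a `km_fit`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.km_fit <- function(object, ...) {
  d <- tidy(object)
  cens <- d[d$n.event == 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$time, y = .data$estimate,
                                  colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::geom_point(data = cens, shape = 3, size = 1.5) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = "Time (months)", y = "Survival probability",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Volcano plot of the t-test filter
#'
#' Feature-wise TILes difference significance: -log10 p against the t
#' statistic, with the retention cutoff drawn as a horizontal line.
#'
#' @param report the filter report tibble from [ttest_filter()] or
#'   [run_selection_pipeline()].
#' @param alpha the cutoff to draw (default 0.005).
#' @return a ggplot.
#' @export
plot_volcano <- function(report, alpha = 0.005) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$t, y = -log10(.data$p))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$stage), alpha = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = "dashed",
                        colour = "red") +
    ggplot2::labs(x = "t statistic (TILes, feature-high vs feature-low)",
                  y = expression(-log[10] ~ p)) +
    ggplot2::theme_minimal()
}

#' Predicted-TILes by response category
#'
#' @param predicted tibble from [predict_tiles()].
#' @param best_response character vector per subject.
#' @return a ggplot.
#' @export
plot_response_scores <- function(predicted, best_response) {
  d <- dplyr::mutate(predicted, response = best_response)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$response, y = .data$score)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "Predicted TILes score") +
    ggplot2::theme_minimal()
}
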