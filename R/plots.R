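# ggplot2 displays for benchmark results and fitted objects.

#' Plot benchmark accuracies
#'
#' Boxplots of per-fold prediction accuracy by method.
#'
#' @param object A `benchmark_result`.
#' @param metric Metric column to display (`"accuracy"`, `"unbiasedness"`,
#'   `"mse"`, `"mae"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_result <- function(object, metric = "accuracy", ...) {
  stopifnot(metric %in% c("accuracy", "unbiasedness", "mse", "mae"))
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = .data$method, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.size = 0.7, fill = "grey85") +
    ggplot2::labs(x = NULL, y = metric) +
    ggplot2::theme_minimal()
}

#' Plot horseshoe shrinkage
#'
#' Posterior mean marker effects along the panel; the horseshoe prior should
#' leave a few large effects and shrink the rest towards zero.
#'
#' @param object An `hs_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hs_fit <- function(object, ...) {
  dat <- dplyr::mutate(object$beta_post, index = dplyr::row_number())
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$index, y = abs(.data$beta))) +
    ggplot2::geom_point(size = 0.6, alpha = 0.7) +
    ggplot2::labs(x = "marker index", y = "|posterior mean effect|") +
    ggplot2::theme_minimal()
}

#' Observed versus predicted corrected phenotypes
#'
#' @param object A `benchmark_result` (with stored predictions).
#' @param ... Unused.
#' @return A ggplot object faceted by method.
#' @export
plot_predictions <- function(object, ...) {
  stopifnot(inherits(object, "benchmark_result"))
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$pv, y = .data$y_c)) +
    ggplot2::geom_point(size = 0.5, alpha = 0.4) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.4, colour = "steelblue") +
    ggplot2::facet_wrap(~method, scales = "free_x") +
    ggplot2::labs(x = "predicted value", y = "corrected phenotype") +
    ggplot2::theme_minimal()
}
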