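#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-fold cross-validation metrics
#'
#' @param object A `cv_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cv_report
#' @export
autoplot.cv_report <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(c("sensitivity", "specificity", "bac"),
                        names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$fold), y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = object$mean$bac, linetype = "dashed") +
    ggplot2::labs(x = "outer fold", y = NULL, title = object$name,
                  subtitle = sprintf("mean BAC %.3f", object$mean$bac)) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot routed cases by traffic-light colour and certainty
#'
#' @param object A `routing_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot routing_result
#' @export
autoplot.routing_result <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$probability,
                                       fill = .data$colour)) +
    ggplot2::geom_histogram(bins = 30, boundary = 0) +
    ggplot2::scale_fill_manual(values = c(green = "#2e7d32", yellow = "#f9a825",
                                          red = "#c62828")) +
    ggplot2::facet_wrap(~ step, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "predicted probability of depression", y = "cases") +
    ggplot2::theme_minimal()
}

#' Plot Gaussian-mixture model-selection criteria
#'
#' @param object A `gmm_selection`.
#' @param ... Unused.
#' @return A ggplot of BIC and AIC against the number of components.
#' @method autoplot gmm_selection
#' @export
autoplot.gmm_selection <- function(object, ...) {
  df <- object$candidates |>
    tidyr::pivot_longer(c("aic", "bic"), names_to = "criterion", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$value,
                                   colour = .data$covariance)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~ criterion, scales = "free_y") +
    ggplot2::labs(x = "components", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot feature hit rates from a shadow-feature selection
#'
#' @param object A `boruta_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot boruta_result
#' @export
autoplot.boruta_result <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$feature, .data$hits),
                                   y = .data$hits / .data$iterations,
                                   fill = .data$decision)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "fraction of iterations beating the best shadow") +
    ggplot2::theme_minimal()
}
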