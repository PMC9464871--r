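#' Plot an accuracy/retention curve
#'
#' Retained tile count and accuracy on retained tiles against the
#' agreement threshold (the selective-prediction trade-off).
#'
#' @param object An `agreement_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.agreement_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(
    dplyr::select(object, "threshold", "n_retained", "accuracy"),
    c("n_retained", "accuracy"), names_to = "metric")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$threshold, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), scales = "free_y") +
    ggplot2::labs(x = "ensemble agreement threshold (members)", y = NULL,
                  title = "Selective prediction by ensemble agreement") +
    ggplot2::theme_minimal()
}

#' Plot a stratified performance report
#'
#' @param object A `performance_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.performance_report <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = factor(.data$group), y = .data$accuracy)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "group", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' Plot ensemble accuracy against training noise level
#'
#' One line per test stratum (e.g. test site): the noisy-ensemble
#' robustness picture — accuracy on degraded strata rising with
#' moderate label noise while clean strata stay nearly flat.
#'
#' @param results Tibble with columns `rho`, `group`, `accuracy` (and
#'   optionally `repeat_index`, averaged over).
#' @return A ggplot object.
#' @export
plot_noise_sweep <- function(results) {
  df <- results |>
    dplyr::summarise(accuracy = mean(.data$accuracy),
                     .by = c("rho", "group"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho, y = .data$accuracy,
                                   color = factor(.data$group))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "training label noise level", y = "ensemble accuracy",
                  color = "test group") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
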