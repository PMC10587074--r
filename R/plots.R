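# ggplot2 views of the result tables. The tidy TSV tables are the canonical
# output; these plots are quick-look diagnostics.

#' Plot potency value distributions
#'
#' Density of pIC50 per class over the full 5--11 range, with the sub-range
#' boundaries marked — the quick visual check that classes are unimodal with
#' their median in the 7--8 interval and most compounds at intermediate
#' potency.
#'
#' @param classes Compound tibble with `class_id` and `pic50`.
#' @return A ggplot object.
#' @export
plot_potency_distributions <- function(classes) {
  check_columns(classes, c("class_id", "pic50"), "classes")
  ggplot2::ggplot(classes, ggplot2::aes(x = .data$pic50,
                                        colour = .data$class_id)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = c(7, 9), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::scale_x_continuous(limits = c(5, 11)) +
    ggplot2::labs(x = "pIC50", y = "density", colour = "class") +
    ggplot2::theme_minimal()
}

#' Plot benchmark metric distributions
#'
#' Boxplots of per-trial metric values by method, faceted by scope (global
#' and the three potency sub-ranges) and class.
#'
#' @param metrics Metric tibble from [run_benchmark()].
#' @param metric Which metric column to show (default `"mae"`).
#' @return A ggplot object.
#' @export
plot_benchmark <- function(metrics, metric = c("mae", "rmse", "r2")) {
  metric <- match.arg(metric)
  check_columns(metrics, c("method", "scope", metric), "metrics")
  ggplot2::ggplot(metrics,
                  ggplot2::aes(x = .data$method, y = .data[[metric]])) +
    ggplot2::geom_boxplot(outlier.shape = 18) +
    ggplot2::facet_grid(
      rows = if ("class_id" %in% names(metrics)) ggplot2::vars(.data$class_id),
      cols = ggplot2::vars(.data$scope)) +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_minimal()
}

#' Plot ladder learning curves
#'
#' Median (over trials and classes) of a metric against training-set size,
#' per method, faceted by potency sub-range — the learning-curve view in
#' which the MID sub-range stays flat at the median-regression level while
#' LOW/HIGH errors fall with size.
#'
#' @param metrics Metric tibble from [run_ladder()].
#' @param metric Metric column (default `"mae"`).
#' @return A ggplot object.
#' @export
plot_ladder <- function(metrics, metric = c("mae", "rmse", "r2")) {
  metric <- match.arg(metric)
  check_columns(metrics, c("method", "scope", "ladder_size", metric),
                "metrics")
  curve <- metrics |>
    dplyr::filter(.data$scope != "GLOBAL") |>
    dplyr::group_by(.data$method, .data$scope, .data$ladder_size) |>
    dplyr::summarise(value = stats::median(.data[[metric]], na.rm = TRUE),
                     .groups = "drop")
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$ladder_size, y = .data$value,
                                      colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(trans = "log2", breaks = ladder_sizes()) +
    ggplot2::facet_wrap(ggplot2::vars(.data$scope)) +
    ggplot2::labs(x = "training set size", y = paste("median", toupper(metric)),
                  colour = "method") +
    ggplot2::theme_minimal()
}
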