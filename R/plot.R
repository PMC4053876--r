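#' Plot a grid field as a raster map
#'
#' @param object A [grid_field()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.grid_field <- function(object, ...) {
  df <- grid_to_tibble(object)
  lab <- if (nzchar(object$variable)) object$variable else "value"
  if (nzchar(object$units)) lab <- paste0(lab, " (", object$units, ")")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85", name = lab) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' Plot per-run validation performance of repeated training
#'
#' Validation correlation of every random-sampling run, with the selected
#' best run highlighted.
#'
#' @param object A `train_report` from [train_lm()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.train_report <- function(object, ...) {
  df <- object$runs
  best <- df[df$run == object$best_run, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$run, y = .data$r)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_point(data = best, colour = "red", size = 3) +
    ggplot2::labs(x = "training run", y = "validation Pearson r") +
    ggplot2::theme_minimal()
}

#' Loss trajectory of the best training run
#'
#' Accepted Levenberg-Marquardt steps never increase the training SSE, so
#' this curve is non-increasing.
#'
#' @param report A `train_report`.
#' @return A ggplot.
#' @export
plot_loss_trajectory <- function(report) {
  stopifnot(inherits(report, "train_report"))
  df <- tibble::tibble(step = seq_along(report$loss_trajectory) - 1,
                       sse = report$loss_trajectory)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$step, y = .data$sse)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "accepted step", y = "training SSE (standardised)") +
    ggplot2::theme_minimal()
}

#' Compare per-capita and population-weighted exposure across zones
#'
#' @param object A `zonal_exposure` tibble from [zonal_report()].
#' @param ... Unused.
#' @return A ggplot with one panel per statistic.
#' @export
autoplot.zonal_exposure <- function(object, ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(c("pc_pm25", "pw_pm25"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = stats::reorder(.data$zone_name,
                                                      .data$value),
                                   y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::coord_flip() +
    ggplot2::facet_wrap(~statistic, scales = "free_x") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
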