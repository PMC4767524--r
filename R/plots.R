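#' Plot a prey trajectory
#'
#' Paths of every agent over the trial, with the target highlighted.
#'
#' @param object A `"prey_trajectory"` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prey_trajectory
#' @export
autoplot.prey_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       group = .data$agent)) +
    ggplot2::geom_path(ggplot2::aes(colour = .data$is_target,
                                    linewidth = .data$is_target),
                       alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "orangered"),
                                 name = "target") +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.3, `TRUE` = 0.9),
                                    guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (D)", y = "y (D)") +
    ggplot2::theme_minimal()
}

#' Plot a trial record
#'
#' Prey paths plus the predator cursor path and the capture point.
#'
#' @param object A `"prey_trial"` record.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prey_trial
#' @export
autoplot.prey_trial <- function(object, ...) {
  p <- autoplot.prey_trajectory(object$trajectory) +
    ggplot2::geom_path(data = object$cursor,
                       ggplot2::aes(.data$x, .data$y, group = NULL),
                       colour = "red3", linewidth = 0.5)
  if (!is.null(object$click)) {
    p <- p + ggplot2::annotate("point", x = object$click$x,
                               y = object$click$y, shape = 4, size = 3,
                               colour = "red3")
  }
  p
}

#' Plot per-frame kinetic series
#'
#' Faceted time series of the windowed kinetic metrics of one or more
#' trials (long format: bind several [kinetic_series()] outputs with an
#' identifying column and pass `group`).
#'
#' @param series A [kinetic_series()] tibble.
#' @param metrics Which metric columns to show.
#' @return A ggplot object.
#' @export
plot_kinetic_series <- function(series,
                                metrics = c("v_T", "v_G", "rho", "nnd",
                                            "vpa")) {
  metrics <- intersect(metrics, names(series))
  long <- tidyr::pivot_longer(series, dplyr::all_of(metrics),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$step, .data$value)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "step (frame)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a collinearity screen
#'
#' Tile map of the pairwise Spearman correlations among the screened
#' metrics, with flagged pairs outlined.
#'
#' @param object A `"collinearity_screen"` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot collinearity_screen
#' @export
autoplot.collinearity_screen <- function(object, ...) {
  rho <- object$spearman
  df <- tibble::as_tibble(as.table(rho), .name_repair = ~c("a", "b", "r"))
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r)),
                       size = 3) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman r") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
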