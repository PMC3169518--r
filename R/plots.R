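# ggplot2 visualisations.

#' @importFrom ggplot2 ggplot aes geom_raster geom_line geom_col geom_rect
#'   geom_step labs scale_fill_viridis_c facet_wrap theme_minimal
NULL

#' Plot a free-energy landscape
#'
#' Filled raster of the free energy over the order-parameter plane;
#' unoccupied cells are blank.
#'
#' @param object A `fel_grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fel_grid <- function(object, ...) {
  cells <- object$cells[is.finite(object$cells$deltaA), , drop = FALSE]
  ggplot(cells, aes(x = .data$x_center, y = .data$y_center,
                    fill = .data$deltaA)) +
    geom_raster() +
    scale_fill_viridis_c(name = expression(Delta * A ~ "(kJ/mol)")) +
    labs(x = object$x_axis$name, y = object$y_axis$name) +
    theme_minimal()
}

#' Plot a TS residence-time distribution with its monoexponential fit
#'
#' @param object A `lifetime_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lifetime_fit <- function(object, ...) {
  h <- object$histogram
  p <- ggplot(h, aes(x = .data$t_ps, y = .data$count)) +
    geom_col(width = object$frame_interval * 0.9, fill = "grey70") +
    labs(x = "TS residence time (ps)", y = "excursions") +
    theme_minimal()
  if (object$method == "wls") {
    p <- p + geom_line(aes(y = .data$fitted), linetype = "dashed",
                       colour = "black")
  }
  p
}

#' State timeline of one or more trajectories
#'
#' Step plot of the U/TS/F occupancy in time, one facet per trajectory.
#'
#' @param labels State label tibble.
#' @return A ggplot.
#' @export
plot_state_timeline <- function(labels) {
  labels$state <- factor(labels$state, levels = c("U", "TS", "F"))
  ggplot(labels, aes(x = .data$time_ps / 1000, y = .data$state,
                     group = .data$traj_id)) +
    geom_step() +
    facet_wrap(~traj_id, ncol = 1) +
    labs(x = "time (ns)", y = NULL) +
    theme_minimal()
}

#' Distance time courses along forward reactive paths
#'
#' One facet per excursion, distances coloured by observable, with the TS
#' span shaded.
#'
#' @param timecourse Output of [reactive_timecourse()].
#' @return A ggplot.
#' @export
plot_timecourse <- function(timecourse) {
  ts_span <- timecourse |>
    dplyr::filter(.data$in_ts) |>
    dplyr::group_by(.data$segment_id) |>
    dplyr::summarise(start = min(.data$time_ps), end = max(.data$time_ps),
                     .groups = "drop")
  ggplot(timecourse, aes(x = .data$time_ps, y = .data$distance_nm,
                         colour = .data$observable)) +
    geom_rect(data = ts_span,
              aes(xmin = .data$start, xmax = .data$end),
              ymin = -Inf, ymax = Inf, fill = "grey85", colour = NA,
              inherit.aes = FALSE) +
    geom_line() +
    facet_wrap(~segment_id, scales = "free_x") +
    labs(x = "time (ps)", y = "distance (nm)") +
    theme_minimal()
}
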