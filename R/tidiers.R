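# broom-style tidiers for the package's fitted objects.

#' Tidy a free-energy landscape grid
#'
#' @param x A `fel_grid`.
#' @param occupied_only Drop unoccupied cells (default `TRUE`).
#' @param ... Unused.
#' @return The cell table as a tibble, with the axis variable names as
#'   `x_name` / `y_name` attributes.
#' @export
tidy.fel_grid <- function(x, occupied_only = TRUE, ...) {
  cells <- x$cells
  if (occupied_only) cells <- cells[cells$count > 0, , drop = FALSE]
  attr(cells, "x_name") <- x$x_axis$name
  attr(cells, "y_name") <- x$y_axis$name
  cells
}

#' @rdname tidy.fel_grid
#' @export
glance.fel_grid <- function(x, ...) {
  tibble(
    n_frames = x$n_frames,
    n_occupied = sum(x$cells$count > 0),
    n_bins = x$x_axis$n_bins,
    temperature = x$temperature,
    ref_x = axis_centers(x$x_axis)[x$ref_cell[1]],
    ref_y = axis_centers(x$y_axis)[x$ref_cell[2]],
    max_deltaA = max(x$cells$deltaA[is.finite(x$cells$deltaA)])
  )
}

#' Tidy a TS lifetime fit
#'
#' @param x A `lifetime_fit`.
#' @param ... Unused.
#' @return One row per fitted quantity with estimate and standard error.
#' @export
tidy.lifetime_fit <- function(x, ...) {
  n <- x$n_events
  tibble(
    term = c("tau", "p_fold"),
    estimate = c(x$tau, x$p_fold),
    std.error = c(x$tau_error, sqrt(x$p_fold * x$p_unfold / n))
  )
}

#' @rdname tidy.lifetime_fit
#' @export
glance.lifetime_fit <- function(x, ...) {
  tibble(
    tau_ps = x$tau, tau_error_ps = x$tau_error,
    correlation = x$correlation, n_events = x$n_events,
    p_fold = x$p_fold, p_unfold = x$p_unfold, method = x$method
  )
}
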