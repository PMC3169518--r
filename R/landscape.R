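# Two-dimensional free-energy landscape by Boltzmann inversion of the
# binned probability density over a pair of order parameters:
#
#   deltaA_i = -R T ln(p_i / p_ref),   R = 0.008314 kJ/(mol K)
#
# with the reference cell the most probable (mode) cell, so deltaA >= 0
# everywhere and unoccupied cells carry +Inf.

make_axis <- function(name, values, n_bins) {
  if (name == "Q") {
    lo <- 0; hi <- 1
  } else {
    lo <- min(values); hi <- max(values)
  }
  if (!(hi > lo)) {
    stop_hairpin(sprintf("axis %s has zero width", name), "degenerate_axis_error")
  }
  list(name = name, lo = lo, hi = hi, n_bins = as.integer(n_bins),
       width = (hi - lo) / n_bins)
}

# Bin index along one axis; final bin is right-closed. Values outside the
# axis range return NA.
bin_index <- function(values, axis) {
  idx <- floor((values - axis$lo) / axis$width) + 1L
  idx[values == axis$hi] <- axis$n_bins
  idx[idx < 1L | idx > axis$n_bins] <- NA_integer_
  as.integer(idx)
}

axis_centers <- function(axis) {
  axis$lo + (seq_len(axis$n_bins) - 0.5) * axis$width
}

count_matrix <- function(series, x_axis, y_axis, strict = TRUE) {
  ix <- bin_index(series[[x_axis$name]], x_axis)
  iy <- bin_index(series[[y_axis$name]], y_axis)
  if (strict && (anyNA(ix) || anyNA(iy))) {
    stop_hairpin("frame outside the landscape axis range", "assignment_error")
  }
  ok <- !is.na(ix) & !is.na(iy)
  counts <- matrix(0L, x_axis$n_bins, y_axis$n_bins)
  tab <- table(factor(ix[ok], levels = seq_len(x_axis$n_bins)),
               factor(iy[ok], levels = seq_len(y_axis$n_bins)))
  counts[] <- as.integer(tab)
  counts
}

delta_a_from_counts <- function(counts, ref_count, temperature) {
  out <- matrix(Inf, nrow(counts), ncol(counts))
  occ <- counts > 0
  out[occ] <- -R_GAS * temperature * log(counts[occ] / ref_count)
  out
}

# Mode cell; ties broken by lowest x index, then lowest y index.
mode_cell <- function(counts) {
  best <- max(counts)
  hits <- which(counts == best, arr.ind = TRUE)
  hits <- hits[order(hits[, 1], hits[, 2]), , drop = FALSE]
  as.integer(hits[1, ])
}

#' Build a free-energy landscape over two order parameters
#'
#' Pools all frames of `series`, bins them on an `n_bins` x `n_bins` grid
#' and converts cell probabilities to free energies by Boltzmann inversion
#' relative to the most probable cell. The Q axis is fixed to `[0, 1]`;
#' other axes span the pooled data range with a right-closed final bin.
#'
#' @param series Order-parameter tibble (may pool several trajectories);
#'   must contain the `x` and `y` columns and `traj_id`.
#' @param x,y Names of the axis variables (default `"Q"` and `"R"`).
#' @param n_bins Bins per axis (default 40, i.e. 1600 cells).
#' @param temperature Temperature in K (default 300).
#' @return An object of class `fel_grid`: list with `cells` (tibble of
#'   `ix`, `iy`, `x_center`, `y_center`, `count`, `prob`, `deltaA`,
#'   `sigma`), axis descriptors, `ref_cell`, `temperature`, `n_frames`.
#' @export
build_landscape <- function(series, x = "Q", y = "R", n_bins = 40,
                            temperature = 300) {
  if (nrow(series) < 1) stop_hairpin("no frames", "empty_input_error")
  if (n_bins < 2) stop_hairpin("n_bins must be >= 2", "configuration_error")
  for (v in c(x, y)) {
    if (!v %in% names(series)) {
      stop_hairpin(paste0("series lacks variable ", v), "configuration_error")
    }
  }
  x_axis <- make_axis(x, series[[x]], n_bins)
  y_axis <- make_axis(y, series[[y]], n_bins)
  counts <- count_matrix(series, x_axis, y_axis)
  ref <- mode_cell(counts)
  deltaA <- delta_a_from_counts(counts, counts[ref[1], ref[2]], temperature)
  cells <- tidyr::expand_grid(ix = seq_len(n_bins), iy = seq_len(n_bins))
  cells$x_center <- axis_centers(x_axis)[cells$ix]
  cells$y_center <- axis_centers(y_axis)[cells$iy]
  cells$count <- counts[cbind(cells$ix, cells$iy)]
  cells$prob <- cells$count / sum(counts)
  cells$deltaA <- deltaA[cbind(cells$ix, cells$iy)]
  cells$sigma <- NA_real_
  structure(
    list(cells = cells, x_axis = x_axis, y_axis = y_axis,
         ref_cell = ref, temperature = temperature,
         n_frames = sum(counts), groups = NULL),
    class = "fel_grid"
  )
}

#' @export
print.fel_grid <- function(x, ...) {
  occ <- sum(x$cells$count > 0)
  cat(sprintf("<fel_grid> %s x %s, %d x %d cells (%d occupied), %d frames, T = %g K\n",
              x$x_axis$name, x$y_axis$name, x$x_axis$n_bins, x$y_axis$n_bins,
              occ, x$n_frames, x$temperature))
  cat(sprintf("  reference (mode) cell: (%d, %d) at %s = %.3g, %s = %.3g\n",
              x$ref_cell[1], x$ref_cell[2],
              x$x_axis$name, axis_centers(x$x_axis)[x$ref_cell[1]],
              x$y_axis$name, axis_centers(x$y_axis)[x$ref_cell[2]]))
  invisible(x)
}

# Split trajectory ids into M contiguous groups of (near) equal size.
default_groups <- function(traj_ids, m) {
  ids <- sort(unique(traj_ids))
  if (length(ids) < m) {
    stop_hairpin("fewer trajectories than subset groups", "configuration_error")
  }
  grp <- rep(seq_len(m), each = ceiling(length(ids) / m))[seq_along(ids)]
  stats::setNames(grp, ids)
}

#' Subset-based standard errors of the free energy
#'
#' Splits the trajectories into `M` disjoint groups, recomputes the free
#' energy of every cell within each subset (anchored to the global
#' reference cell), and reports per cell the standard error of the mean
#' across subsets, sigma = sd(subset values) / sqrt(M). Cells unoccupied in
#' any subset (or whose subset lacks the reference cell) get `NA`.
#'
#' @param grid A `fel_grid`.
#' @param series The same pooled order-parameter tibble used to build it.
#' @param groups Either the number of groups M (trajectories are split into
#'   contiguous sorted groups) or a named vector mapping `traj_id` to group.
#' @return The grid with its `cells$sigma` column filled.
#' @export
subset_errors <- function(grid, series, groups = 3) {
  if (is.numeric(groups) && length(groups) == 1) {
    if (groups < 2) stop_hairpin("need at least 2 subsets", "configuration_error")
    groups <- default_groups(series$traj_id, as.integer(groups))
  }
  gid <- groups[as.character(series$traj_id)]
  if (anyNA(gid)) {
    stop_hairpin("every trajectory must be assigned to exactly one group",
                 "configuration_error")
  }
  labels <- sort(unique(groups))
  m <- length(labels)
  if (m < 2) stop_hairpin("need at least 2 subsets", "configuration_error")
  ref <- grid$ref_cell
  vals <- array(NA_real_, dim = c(grid$x_axis$n_bins, grid$y_axis$n_bins, m))
  for (k in seq_len(m)) {
    sub <- series[gid == labels[k], , drop = FALSE]
    counts <- count_matrix(sub, grid$x_axis, grid$y_axis)
    ref_count <- counts[ref[1], ref[2]]
    if (ref_count > 0) {
      da <- delta_a_from_counts(counts, ref_count, grid$temperature)
      da[!is.finite(da)] <- NA_real_
      vals[, , k] <- da
    }
  }
  sig <- apply(vals, c(1, 2), function(v) {
    if (anyNA(v)) NA_real_ else stats::sd(v) / sqrt(length(v))
  })
  grid$cells$sigma <- sig[cbind(grid$cells$ix, grid$cells$iy)]
  grid$cells$sigma[grid$cells$count == 0] <- NA_real_
  grid$groups <- groups
  grid
}

#' Time convergence of a cell's free energy
#'
#' Recomputes the free energy of one grid cell using only frames up to each
#' checkpoint time (each trajectory truncated at the same elapsed time on
#' its own clock), on the axes and reference cell of the full grid.
#'
#' @param grid A `fel_grid`.
#' @param series The pooled order-parameter tibble used to build it.
#' @param cell Integer vector `c(ix, iy)`.
#' @param checkpoints Increasing vector of elapsed times, ps.
#' @return Tibble with `checkpoint_ps`, `elapsed_us` (pooled sampling time
#'   actually used) and `deltaA` (`NA` where the cell or the reference cell
#'   has not yet been visited).
#' @export
convergence_trace <- function(grid, series, cell, checkpoints) {
  if (is.unsorted(checkpoints, strictly = TRUE)) {
    stop_hairpin("checkpoints must be strictly increasing", "configuration_error")
  }
  ref <- grid$ref_cell
  rows <- purrr::map(checkpoints, function(tp) {
    sub <- series[series$time_ps <= tp, , drop = FALSE]
    elapsed <- sum(tapply(series$time_ps, series$traj_id,
                          function(tt) min(tp, max(tt)))) / 1e6
    if (nrow(sub) == 0) {
      return(tibble(checkpoint_ps = tp, elapsed_us = elapsed, deltaA = NA_real_))
    }
    counts <- count_matrix(sub, grid$x_axis, grid$y_axis)
    rc <- counts[ref[1], ref[2]]
    cc <- counts[cell[1], cell[2]]
    da <- if (rc > 0 && cc > 0) -R_GAS * grid$temperature * log(cc / rc) else NA_real_
    tibble(checkpoint_ps = tp, elapsed_us = elapsed, deltaA = da)
  })
  dplyr::bind_rows(rows)
}

#' Serialize a landscape grid to CSV + JSON metadata
#'
#' @param grid A `fel_grid`.
#' @param path CSV path for the cell table; axis metadata goes to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_landscape <- function(grid, path) {
  cells <- grid$cells
  cells$deltaA[!is.finite(cells$deltaA)] <- NA_real_
  readr::write_csv(cells, path)
  jsonlite::write_json(
    list(x_axis = grid$x_axis, y_axis = grid$y_axis,
         ref_cell = grid$ref_cell, temperature = grid$temperature,
         n_frames = grid$n_frames),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}
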