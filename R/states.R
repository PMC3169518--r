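# Decomposition of the landscape into folded (F), unfolded (U) and
# transition (TS) states. Basins are operationalized as 8-connected flood
# fills from a seed cell over occupied cells within `basin_cut` kJ/mol of
# the global minimum; every remaining occupied cell is TS.

# 8-connected flood fill over cells with deltaA <= cut, from seed (ix, iy).
flood_fill <- function(deltaA, seed, cut) {
  nx <- nrow(deltaA); ny <- ncol(deltaA)
  inside <- is.finite(deltaA) & deltaA <= cut
  if (!inside[seed[1], seed[2]]) {
    stop_hairpin("seed cell not within the basin cutoff", "configuration_error")
  }
  visited <- matrix(FALSE, nx, ny)
  queue <- matrix(seed, ncol = 2)
  visited[seed[1], seed[2]] <- TRUE
  offs <- expand.grid(dx = -1:1, dy = -1:1)
  offs <- offs[!(offs$dx == 0 & offs$dy == 0), ]
  while (nrow(queue) > 0) {
    cur <- queue[1, , drop = FALSE]
    queue <- queue[-1, , drop = FALSE]
    for (k in seq_len(nrow(offs))) {
      xi <- cur[1] + offs$dx[k]; yi <- cur[2] + offs$dy[k]
      if (xi >= 1 && xi <= nx && yi >= 1 && yi <= ny &&
          !visited[xi, yi] && inside[xi, yi]) {
        visited[xi, yi] <- TRUE
        queue <- rbind(queue, c(xi, yi))
      }
    }
  }
  visited
}

# Occupied local minima: deltaA strictly lower than all 8 neighbours
# (unoccupied neighbours count as +Inf).
local_minima <- function(deltaA) {
  nx <- nrow(deltaA); ny <- ncol(deltaA)
  padded <- matrix(Inf, nx + 2, ny + 2)
  padded[2:(nx + 1), 2:(ny + 1)] <- deltaA
  best_nb <- matrix(Inf, nx, ny)
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nb <- padded[(2 + dx):(nx + 1 + dx), (2 + dy):(ny + 1 + dy)]
    best_nb <- pmin(best_nb, nb)
  }
  which(is.finite(deltaA) & deltaA < best_nb, arr.ind = TRUE)
}

deltaA_matrix <- function(grid) {
  m <- matrix(Inf, grid$x_axis$n_bins, grid$y_axis$n_bins)
  m[cbind(grid$cells$ix, grid$cells$iy)] <- grid$cells$deltaA
  m
}

#' Locate the folded and unfolded basins
#'
#' The folded seed is the grid's reference (global-minimum) cell. The
#' unfolded seed is the lowest-free-energy occupied local minimum that is
#' not 8-connected to the folded seed through cells within `basin_cut` of
#' the global minimum. If every local minimum drains into the folded basin
#' the surface is not two-state under these coordinates and an error is
#' raised.
#'
#' @param grid A `fel_grid`.
#' @param basin_cut Basin depth cutoff, kJ/mol (default 12).
#' @return Object of class `state_defn`: list with `f_seed`, `u_seed`
#'   (each `c(ix, iy)`) and `basin_cut`.
#' @export
find_basins <- function(grid, basin_cut = 12) {
  if (basin_cut <= 0) stop_hairpin("basin_cut must be > 0", "configuration_error")
  da <- deltaA_matrix(grid)
  f_seed <- grid$ref_cell
  f_basin <- flood_fill(da, f_seed, basin_cut)
  minima <- local_minima(da)
  # a second basin must itself lie within the basin depth window; isolated
  # high-free-energy minima are barrier-region sampling noise, not basins
  keep <- !f_basin[minima] & da[minima] <= basin_cut
  candidates <- minima[keep, , drop = FALSE]
  if (nrow(candidates) == 0) {
    stop_hairpin("no second basin: system is single-basin under these coordinates",
                 "single_basin_error")
  }
  vals <- da[candidates]
  u_seed <- as.integer(candidates[which.min(vals), ])
  structure(list(f_seed = as.integer(f_seed), u_seed = u_seed,
                 basin_cut = basin_cut),
            class = "state_defn")
}

#' @export
print.state_defn <- function(x, ...) {
  cat(sprintf("<state_defn> F seed (%d, %d); U seed (%d, %d); basin cut %g kJ/mol\n",
              x$f_seed[1], x$f_seed[2], x$u_seed[1], x$u_seed[2], x$basin_cut))
  invisible(x)
}

state_cell_sets <- function(grid, defn) {
  da <- deltaA_matrix(grid)
  f_set <- flood_fill(da, defn$f_seed, defn$basin_cut)
  u_set <- flood_fill(da, defn$u_seed, defn$basin_cut)
  if (any(f_set & u_set)) {
    stop_hairpin("folded and unfolded basins overlap under this definition",
                 "configuration_error")
  }
  list(f = f_set, u = u_set)
}

#' Label every frame as U, TS or F
#'
#' Frames are assigned to the basin whose flood-filled cell set contains
#' their grid cell; frames in any other occupied cell are transition-state
#' (TS) frames.
#'
#' @param series Order-parameter tibble with the grid's axis variables.
#' @param grid A `fel_grid`.
#' @param defn A [find_basins()] state definition.
#' @return Tibble with `traj_id`, `time_ps`, `state` (`"U"`, `"TS"`, `"F"`).
#' @export
assign_states <- function(series, grid, defn) {
  sets <- state_cell_sets(grid, defn)
  ix <- bin_index(series[[grid$x_axis$name]], grid$x_axis)
  iy <- bin_index(series[[grid$y_axis$name]], grid$y_axis)
  if (anyNA(ix) || anyNA(iy)) {
    stop_hairpin("frame outside the landscape axis range", "assignment_error")
  }
  idx <- cbind(ix, iy)
  state <- rep("TS", nrow(series))
  state[sets$f[idx]] <- "F"
  state[sets$u[idx]] <- "U"
  tibble(traj_id = series$traj_id, time_ps = series$time_ps, state = state)
}

# Maximal runs of equal state per trajectory, with start/end row indices.
state_runs <- function(labels_one) {
  r <- rle(labels_one$state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  tibble(state = r$values, start = starts, end = ends)
}

#' Refine the TSE by excluding false-folded transitions
#'
#' A maximal F residence whose mean turn (N6-G9 Calpha) distance exceeds
#' `turn_native_max` is a "false fold": a conformation satisfying the
#' folded-state definition on the order-parameter plane but with a
#' non-native turn. Such residences are relabelled U, and the TS excursion
#' immediately preceding each one is flagged for exclusion from the
#' reported TSE.
#'
#' @param labels A state label tibble from [assign_states()].
#' @param turn_series Turn-distance tibble from
#'   [compute_distance_series()] on the pair `c(6, 9)`, aligned frame by
#'   frame with `labels`.
#' @param turn_native_max Largest mean turn distance accepted as native, nm
#'   (default 0.8).
#' @return List with `labels` (the input plus a logical `tse_excluded`
#'   column and relabelled states) and `exclusions` (tibble of excluded
#'   spans with their kind).
#' @export
refine_tse <- function(labels, turn_series, turn_native_max = 0.8) {
  joined <- dplyr::left_join(labels, turn_series, by = c("traj_id", "time_ps"))
  if (anyNA(joined$distance_nm)) {
    stop_hairpin("turn series is not aligned with the labels", "configuration_error")
  }
  joined <- joined[order(joined$traj_id, joined$time_ps), , drop = FALSE]
  joined$tse_excluded <- FALSE
  exclusions <- list()
  for (id in unique(joined$traj_id)) {
    sel <- which(joined$traj_id == id)
    runs <- state_runs(joined[sel, , drop = FALSE])
    for (k in seq_len(nrow(runs))) {
      if (runs$state[k] != "F") next
      rows <- sel[runs$start[k]:runs$end[k]]
      if (mean(joined$distance_nm[rows]) <= turn_native_max) next
      joined$state[rows] <- "U"
      exclusions[[length(exclusions) + 1]] <- tibble(
        traj_id = id, kind = "false_fold",
        start_ps = joined$time_ps[rows[1]],
        end_ps = joined$time_ps[rows[length(rows)]]
      )
      if (k > 1 && runs$state[k - 1] == "TS") {
        ts_rows <- sel[runs$start[k - 1]:runs$end[k - 1]]
        joined$tse_excluded[ts_rows] <- TRUE
        exclusions[[length(exclusions) + 1]] <- tibble(
          traj_id = id, kind = "excluded_ts",
          start_ps = joined$time_ps[ts_rows[1]],
          end_ps = joined$time_ps[ts_rows[length(ts_rows)]]
        )
      }
    }
  }
  labels_out <- joined[, c("traj_id", "time_ps", "state", "tse_excluded")]
  list(labels = as_tibble(labels_out),
       exclusions = if (length(exclusions)) dplyr::bind_rows(exclusions)
                    else tibble(traj_id = character(), kind = character(),
                                start_ps = numeric(), end_ps = numeric()))
}

#' Overlap between two transition-state ensembles
#'
#' Fraction of the reference labelling's TS frames that are also TS under
#' the alternative labelling (a directed overlap), together
#' with the symmetric Jaccard index.
#'
#' @param labels_a Reference state labels (e.g. from the Q-R landscape).
#' @param labels_b Alternative state labels (e.g. from the RMSD-Q
#'   landscape) covering the identical frames.
#' @return One-row tibble with `overlap`, `jaccard`, `n_ts_a`, `n_ts_b`,
#'   `n_shared`.
#' @export
tse_overlap <- function(labels_a, labels_b) {
  key_a <- paste(labels_a$traj_id, labels_a$time_ps)
  key_b <- paste(labels_b$traj_id, labels_b$time_ps)
  if (length(key_a) != length(key_b) || !setequal(key_a, key_b)) {
    stop_hairpin("label sets do not cover identical frames", "configuration_error")
  }
  ts_a <- key_a[labels_a$state == "TS"]
  ts_b <- key_b[labels_b$state == "TS"]
  if (length(ts_a) == 0) {
    stop_hairpin("reference labelling has no TS frames", "undefined_overlap_error")
  }
  shared <- length(intersect(ts_a, ts_b))
  tibble(
    overlap = shared / length(ts_a),
    jaccard = shared / length(union(ts_a, ts_b)),
    n_ts_a = length(ts_a), n_ts_b = length(ts_b), n_shared = shared
  )
}
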