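# Synthetic trajectory generator: three-state (U <-> TS <-> F) discrete-time
# Markov kinetics at frame resolution, with either direct order-parameter
# emission (fast path) or toy hairpin coordinates built from per-state
# geometric templates. Every downstream estimator has known ground truth.

hairpin_residues <- function() {
  tibble(
    residue_index = 1:15,
    residue_name = c("SER", "GLU", "SER", "TYR", "ILE", "ASN", "PRO", "ASP",
                     "GLY", "THR", "TRP", "THR", "VAL", "THR", "GLU")
  )
}

#' Generator configuration
#'
#' Bundles the kinetic scheme (mean residence time per state, TS branching
#' probability), the emission model for the order-parameter fast path
#' (state-conditional Gaussians on the Q-R plane), and the per-state toy
#' hairpin geometry targets. Defaults place the folded and unfolded basins
#' at (Q, R) = (0.85, 4.95) and (0.10, 2.10), give the TS a mean residence
#' of 10.2 ps with 52.7% folding commitment, and reproduce the
#' characteristic turn/middle/end distances of the folded state
#' (0.55/0.54/0.42 nm) and transition-state ensemble (0.60/0.72/0.42 nm),
#' including the W11 key-lock contact with the P7/G9 turn sidechains.
#'
#' @param n_traj Number of independent trajectories.
#' @param duration_us Duration of each trajectory, microseconds.
#' @param frame_interval_ps Frame spacing, ps.
#' @param seed Integer seed; all generator randomness derives from it.
#' @param tau_u,tau_ts,tau_f Mean residence times, ps.
#' @param p_fold Probability that a TS excursion exits to the folded state.
#' @param ftsf_nucleus_fraction Fraction of non-reactive FTSF excursions
#'   whose TS frames adopt the folding-nucleus geometry (middle contacts
#'   formed, W11 shifted towards P7).
#' @param noise_sd Isotropic Gaussian coordinate noise, nm.
#' @param ramp_frames Length (frames) of the mechanistic interpolation ramps
#'   into and out of the TS (turn-first approach; concerted middle closure
#'   and W11 release on exit).
#' @param series State-conditional emission table for the fast path:
#'   tibble with `state`, `mu_q`, `mu_r`, `sd_q`, `sd_r`.
#' @param geometry Per-state template parameters; see
#'   [build_state_template()].
#' @return Object of class `generator_config`.
#' @export
generator_config <- function(n_traj = 6, duration_us = 2.5,
                             frame_interval_ps = 10, seed = 1,
                             tau_u = 300, tau_ts = 10.2, tau_f = 600,
                             p_fold = 0.527, ftsf_nucleus_fraction = 0.65,
                             noise_sd = 0.02, ramp_frames = 5,
                             series = NULL, geometry = NULL) {
  series <- series %||% tibble(
    state = c("U", "TS", "F"),
    mu_q = c(0.10, 0.45, 0.85),
    mu_r = c(2.10, 3.50, 4.95),
    sd_q = c(0.05, 0.12, 0.05),
    sd_r = c(0.25, 0.80, 0.25)
  )
  geometry <- geometry %||% list(
    rise = 0.32, u_spacing = 0.175, sc_offset = 0.25,
    f = list(seps = c(0.50, 0.50, 0.54, 0.50, 0.47, 0.42), turn = 0.55),
    ts = list(seps = c(0.60, 0.66, 0.72, 0.58, 0.50, 0.42), turn = 0.60,
              w11_p7 = 0.55, w11_g9 = 0.55),
    nucleus = list(seps = c(0.58, 0.55, 0.54, 0.58, 0.52, 0.50), turn = 0.58,
                   w11_p7 = 0.30)
  )
  cfg <- list(
    n_traj = as.integer(n_traj), duration_us = duration_us,
    frame_interval_ps = frame_interval_ps, seed = as.integer(seed),
    tau_u = tau_u, tau_ts = tau_ts, tau_f = tau_f, p_fold = p_fold,
    ftsf_nucleus_fraction = ftsf_nucleus_fraction,
    noise_sd = noise_sd, ramp_frames = as.integer(ramp_frames),
    series = series, geometry = geometry
  )
  with(cfg, {
    stopifnot(n_traj >= 1, duration_us > 0, frame_interval_ps > 0,
              tau_u > 0, tau_ts > 0, tau_f > 0,
              p_fold >= 0, p_fold <= 1,
              ftsf_nucleus_fraction >= 0, ftsf_nucleus_fraction <= 1,
              noise_sd >= 0, ramp_frames >= 0)
  })
  structure(cfg, class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("<generator_config> %d traj x %g us at %g ps/frame (seed %d)\n",
              x$n_traj, x$duration_us, x$frame_interval_ps, x$seed))
  cat(sprintf("  tau(U/TS/F) = %g/%g/%g ps; p_fold = %g; nucleus fraction = %g\n",
              x$tau_u, x$tau_ts, x$tau_f, x$p_fold, x$ftsf_nucleus_fraction))
  invisible(x)
}

escape_probs <- function(config) {
  dt <- config$frame_interval_ps
  p <- c(U = dt / config$tau_u, TS = dt / config$tau_ts, F = dt / config$tau_f)
  if (any(p > 1)) {
    stop_hairpin(
      "frame interval exceeds a state's mean residence time (escape probability > 1)",
      "resolution_error"
    )
  }
  p
}

#' Analytic stationary occupancy of the kinetic scheme
#'
#' Time-weighted stationary distribution of the three-state chain: sojourn
#' visit frequencies (every second sojourn is TS; the basin after each TS
#' is F with probability `p_fold`) weighted by the mean residence times.
#'
#' @param config A [generator_config()].
#' @return Tibble with `state` and `occupancy` summing to 1.
#' @export
stationary_occupancy <- function(config) {
  w <- c(U = 0.5 * (1 - config$p_fold) * config$tau_u,
         TS = 0.5 * config$tau_ts,
         F = 0.5 * config$p_fold * config$tau_f)
  tibble(state = names(w), occupancy = as.numeric(w / sum(w)))
}

# One trajectory's sojourn sequence, truncated to n_frames.
sim_sojourns <- function(n_frames, p_esc, p_fold) {
  states <- character(0)
  lens <- integer(0)
  mean_cycle <- 1 / p_esc[["TS"]] +
    (1 - p_fold) / p_esc[["U"]] + p_fold / p_esc[["F"]]
  cur_basin <- "U"
  while (sum(lens) < n_frames) {
    k <- max(64L, ceiling((n_frames - sum(lens)) / mean_cycle * 1.5))
    basins <- c(cur_basin,
                if (k > 1) c("F", "U")[1 + (runif(k - 1) > p_fold)])
    batch_states <- as.vector(rbind(basins, "TS"))
    p_basin <- p_esc[basins]
    len_basin <- 1L + stats::rgeom(k, p_basin)
    len_ts <- 1L + stats::rgeom(k, p_esc[["TS"]])
    batch_lens <- as.vector(rbind(len_basin, len_ts))
    states <- c(states, batch_states)
    lens <- c(lens, batch_lens)
    cur_basin <- c("F", "U")[1 + (runif(1) > p_fold)]
  }
  cum <- cumsum(lens)
  last <- which(cum >= n_frames)[1]
  states <- states[seq_len(last)]
  lens <- lens[seq_len(last)]
  lens[last] <- lens[last] - (cum[last] - n_frames)
  tibble(state = states, len = as.integer(lens),
         end = cumsum(as.integer(lens))) |>
    dplyr::mutate(start = .data$end - .data$len + 1L)
}

#' Simulate the hidden state sequence
#'
#' Discrete-time Markov chain at frame resolution: each state is left with
#' per-frame probability `frame_interval / tau_state`; a TS exit commits to
#' F with probability `p_fold`, otherwise U; basin exits always enter TS.
#' Trajectories start unfolded.
#'
#' @param config A [generator_config()].
#' @return Object of class `ground_truth`: list with `states` (tibble
#'   `traj_id`, `frame`, `time_ps`, `state`), `excursions` (one row per TS
#'   sojourn with origin/destination/class, frame span and nucleus flag;
#'   boundary excursions have `NA` destination), `stationary` and `config`.
#' @export
simulate_states <- function(config) {
  p_esc <- escape_probs(config)
  set.seed(config$seed)
  dt <- config$frame_interval_ps
  n_frames <- round(config$duration_us * 1e6 / dt)
  if (n_frames < 2) stop_hairpin("duration shorter than two frames", "configuration_error")
  states <- list()
  excursions <- list()
  for (tr in seq_len(config$n_traj)) {
    id <- sprintf("traj%02d", tr)
    soj <- sim_sojourns(n_frames, p_esc, config$p_fold)
    states[[tr]] <- tibble(
      traj_id = id,
      frame = seq_len(n_frames),
      time_ps = (seq_len(n_frames) - 1) * dt,
      state = rep(soj$state, soj$len)
    )
    is_ts <- which(soj$state == "TS")
    if (length(is_ts) > 0) {
      exc <- tibble(
        traj_id = id,
        origin = soj$state[is_ts - 1L],
        destination = ifelse(is_ts + 1L <= nrow(soj), soj$state[is_ts + 1L],
                             NA_character_),
        start_frame = soj$start[is_ts], end_frame = soj$end[is_ts],
        n_frames = soj$len[is_ts]
      )
      exc$class <- ifelse(is.na(exc$destination), NA_character_,
                          paste0(exc$origin, "TS", exc$destination))
      exc$start_ps <- (exc$start_frame - 1) * dt
      exc$end_ps <- (exc$end_frame - 1) * dt
      exc$nucleus <- FALSE
      ftsf <- which(!is.na(exc$class) & exc$class == "FTSF")
      if (length(ftsf) > 0) {
        exc$nucleus[ftsf] <- stats::rbinom(length(ftsf), 1,
                                           config$ftsf_nucleus_fraction) == 1
      }
      excursions[[tr]] <- exc
    }
  }
  structure(
    list(states = dplyr::bind_rows(states),
         excursions = if (length(excursions)) dplyr::bind_rows(excursions)
                      else tibble(traj_id = character(), origin = character(),
                                  destination = character(),
                                  start_frame = integer(), end_frame = integer(),
                                  n_frames = integer(), class = character(),
                                  start_ps = numeric(), end_ps = numeric(),
                                  nucleus = logical()),
         stationary = stationary_occupancy(config),
         config = config),
    class = "ground_truth"
  )
}

#' @export
print.ground_truth <- function(x, ...) {
  cat(sprintf("<ground_truth> %d frames, %d trajectories, %d TS excursions\n",
              nrow(x$states), length(unique(x$states$traj_id)),
              nrow(x$excursions)))
  invisible(x)
}

#' Emit order parameters directly (fast path)
#'
#' Samples per-frame (Q, R) from the state-conditional Gaussians of the
#' configuration, bypassing geometry; Q is clipped to `[0, 1]`.
#'
#' @param truth A [simulate_states()] result.
#' @param config The same [generator_config()].
#' @return Order-parameter tibble (`traj_id`, `time_ps`, `R`, `Q`).
#' @export
emit_series_only <- function(truth, config = truth$config) {
  set.seed(config$seed + 1L)
  em <- config$series
  st <- truth$states
  row <- match(st$state, em$state)
  n <- nrow(st)
  q <- pmin(pmax(rnorm(n, em$mu_q[row], em$sd_q[row]), 0), 1)
  r <- pmax(rnorm(n, em$mu_r[row], em$sd_r[row]), 1e-3)
  tibble(traj_id = st$traj_id, time_ps = st$time_ps, R = r, Q = q)
}

# ---- geometry ---------------------------------------------------------

# Point at given distances from a and b, offset perpendicular to the a-b
# axis (used to park the W11 sidechain between the P7 and G9 sidechains).
place_between <- function(a, b, da, db) {
  ab <- b - a
  l <- sqrt(sum(ab^2))
  if (l > da + db || l < abs(da - db)) {
    stop_hairpin(sprintf(
      "infeasible key-lock geometry: anchors %.3f nm apart, radii %.3f / %.3f",
      l, da, db), "construction_error")
  }
  u <- ab / l
  t <- (da^2 - db^2 + l^2) / (2 * l)
  h2 <- da^2 - t^2
  h <- sqrt(max(h2, 0))
  e <- c(1, 0, 0)
  if (abs(sum(e * u)) > 0.9) e <- c(0, 1, 0)
  v <- e - sum(e * u) * u
  v <- v / sqrt(sum(v^2))
  a + t * u + h * v
}

# Calpha positions for a hairpin-like template from the six inter-strand
# separations (pairs (6,10),(5,11),(4,12),(3,13),(2,14),(1,15)) and the
# turn (6,9) distance target; the turn residue 9 position is solved so the
# target is met exactly.
hairpin_ca <- function(seps, turn, rise) {
  ca <- matrix(NA_real_, 15, 3)
  for (k in 0:5) {
    ca[6 - k, ] <- c(rise * k, seps[k + 1] / 2, 0)
    ca[10 + k, ] <- c(rise * k, -seps[k + 1] / 2, 0)
  }
  ca[7, ] <- c(-0.30, ca[6, 2] - 0.03, 0.05)
  ca[8, ] <- c(-0.45, 0, 0.10)
  y9 <- -seps[1] / 2 + 0.05
  z9 <- 0.05
  dx2 <- turn^2 - (y9 - ca[6, 2])^2 - z9^2
  if (dx2 <= 0) {
    stop_hairpin("infeasible turn distance target for this strand separation",
                 "construction_error")
  }
  ca[9, ] <- c(-sqrt(dx2), y9, z9)
  ca
}

template_atoms_meta <- function() {
  res <- hairpin_residues()
  meta <- purrr::map(1:15, function(i) {
    rows <- tibble(residue_index = i,
                   residue_name = res$residue_name[i],
                   atom_name = "CA", is_backbone = TRUE)
    if (res$residue_name[i] != "GLY") {
      rows <- dplyr::bind_rows(rows, tibble(
        residue_index = i, residue_name = res$residue_name[i],
        atom_name = "CB", is_backbone = FALSE))
    }
    rows
  })
  dplyr::bind_rows(meta)
}

#' Noiseless per-state template geometry
#'
#' Builds the toy hairpin conformation used by the coordinate emitter for
#' one state: 15 residues with one Calpha and one pseudo-sidechain atom
#' (CB) each; glycine 9 has no sidechain atom. The folded, TS and nucleus
#' templates are two flared antiparallel strands plus a turn, with the
#' inter-strand separations, the turn distance, and (for TS/nucleus) the
#' W11 sidechain position hitting the configured targets exactly; the
#' unfolded template is an open chain tuned so its R parameter falls in
#' the unfolded basin.
#'
#' @param config A [generator_config()].
#' @param state `"F"`, `"TS"`, `"U"` or `"nucleus"`.
#' @return Atom tibble (one frame).
#' @export
build_state_template <- function(config = generator_config(),
                                 state = c("F", "TS", "U", "nucleus")) {
  state <- match.arg(state)
  g <- config$geometry
  meta <- template_atoms_meta()
  if (state == "U") {
    alt <- rep(c(-1, 1), length.out = 15)  # parity of residue index (odd -> -1)
    ca <- cbind((0:14) * g$u_spacing, 0, 0.04 * alt)
  } else {
    p <- g[[tolower(state)]]
    ca <- hairpin_ca(p$seps, p$turn, g$rise)
  }
  cb <- ca + cbind(0, 0, g$sc_offset * rep(c(-1, 1), length.out = 15))
  if (state %in% c("TS", "nucleus")) {
    p <- g[[tolower(state)]]
    p7 <- cb[7, ]
    g9 <- ca[9, ]  # glycine sidechain proxy
    if (state == "TS") {
      cb[11, ] <- place_between(p7, g9, p$w11_p7, p$w11_g9)
    } else {
      u <- (g9 - p7) / sqrt(sum((g9 - p7)^2))
      cb[11, ] <- p7 + p$w11_p7 * u
    }
  }
  xyz <- matrix(NA_real_, nrow(meta), 3)
  xyz[meta$atom_name == "CA", ] <- ca[meta$residue_index[meta$atom_name == "CA"], ]
  is_cb <- meta$atom_name == "CB"
  xyz[is_cb, ] <- cb[meta$residue_index[is_cb], ]
  out <- meta
  out$x <- xyz[, 1]; out$y <- xyz[, 2]; out$z <- xyz[, 3]
  out
}

# Templates as flat coordinate rows (x1 y1 z1 x2 y2 z2 ...).
template_matrix <- function(config) {
  states <- c("F", "TS", "U", "nucleus")
  rows <- vapply(states, function(s) {
    tmpl <- build_state_template(config, s)
    as.vector(t(as.matrix(tmpl[, c("x", "y", "z")])))
  }, numeric(3 * nrow(template_atoms_meta())))
  t(rows)
}

#' Emit toy hairpin coordinates for a simulated state sequence
#'
#' Every frame takes the template of its hidden state plus isotropic
#' Gaussian noise. Entries into the TS are preceded by an interpolation
#' ramp from the origin template (turn-first approach: the open-chain
#' template already has the turn residues close, so the turn is formed
#' before the ends meet), and TS exits are followed by a ramp into the
#' destination template (concerted middle closure and W11 release). The TS
#' frames of FTSF excursions flagged as nucleus use the folding-nucleus
#' template.
#'
#' @param truth A [simulate_states()] result.
#' @param config The same [generator_config()].
#' @return List with `traj` (trajectory tibble over all trajectories) and
#'   `ref` (a [build_reference()] object built from the noiseless folded
#'   template).
#' @export
emit_coordinates <- function(truth, config = truth$config) {
  set.seed(config$seed + 2L)
  tm <- template_matrix(config)
  state_row <- c(F = 1L, TS = 2L, U = 3L)
  meta <- template_atoms_meta()
  n_atoms <- nrow(meta)
  dt <- config$frame_interval_ps
  out <- list()
  for (id in unique(truth$states$traj_id)) {
    st <- truth$states[truth$states$traj_id == id, , drop = FALSE]
    n <- nrow(st)
    main <- state_row[st$state]
    # nucleus excursions override their TS frames
    exc <- truth$excursions[truth$excursions$traj_id == id, , drop = FALSE]
    nuc <- exc[!is.na(exc$class) & exc$class == "FTSF" & exc$nucleus, , drop = FALSE]
    for (k in seq_len(nrow(nuc))) {
      main[nuc$start_frame[k]:nuc$end_frame[k]] <- 4L
    }
    to <- main
    alpha <- numeric(n)
    r <- config$ramp_frames
    if (r > 0 && nrow(exc) > 0) {
      soj <- state_runs(st)
      ts_runs <- which(soj$state == "TS")
      for (k in ts_runs) {
        ts_var <- main[soj$start[k]]
        if (k > 1) {  # approach ramp in the tail of the preceding sojourn
          prev_len <- soj$end[k - 1] - soj$start[k - 1] + 1L
          rr <- min(r, prev_len %/% 2L)
          if (rr > 0) {
            rows <- (soj$end[k - 1] - rr + 1L):soj$end[k - 1]
            to[rows] <- ts_var
            alpha[rows] <- seq_len(rr) / (rr + 1)
          }
        }
        if (k < nrow(soj)) {  # exit ramp at the head of the next sojourn
          next_len <- soj$end[k + 1] - soj$start[k + 1] + 1L
          rr <- min(r, ceiling(next_len / 2))
          if (rr > 0) {
            rows <- soj$start[k + 1]:(soj$start[k + 1] + rr - 1L)
            main[rows] <- ts_var
            to[rows] <- state_row[soj$state[k + 1]]
            alpha[rows] <- seq_len(rr) / (rr + 1)
          }
        }
      }
    }
    coords <- (1 - alpha) * tm[main, , drop = FALSE] +
      alpha * tm[to, , drop = FALSE]
    if (config$noise_sd > 0) {
      coords <- coords + rnorm(length(coords), sd = config$noise_sd)
    }
    xs <- coords[, seq(1, 3 * n_atoms, 3), drop = FALSE]
    ys <- coords[, seq(2, 3 * n_atoms, 3), drop = FALSE]
    zs <- coords[, seq(3, 3 * n_atoms, 3), drop = FALSE]
    fr <- tibble(
      traj_id = id,
      frame = rep(st$frame, each = n_atoms),
      time_ps = rep(st$time_ps, each = n_atoms),
      residue_index = rep(meta$residue_index, n),
      residue_name = rep(meta$residue_name, n),
      atom_name = rep(meta$atom_name, n),
      is_backbone = rep(meta$is_backbone, n),
      x = as.vector(t(xs)), y = as.vector(t(ys)), z = as.vector(t(zs))
    )
    out[[length(out) + 1]] <- fr
  }
  ref <- build_reference(build_state_template(config, "F"))
  list(traj = dplyr::bind_rows(out), ref = ref)
}

#' Simulate a complete synthetic data set
#'
#' Convenience wrapper: [simulate_states()] plus either the coordinate
#' emitter or the order-parameter fast path.
#'
#' @param config A [generator_config()].
#' @param coordinates If `TRUE` emit toy hairpin coordinates; otherwise
#'   only the order-parameter series.
#' @return List with `truth` and either (`traj`, `ref`) or `series`.
#' @export
simulate_trajectory <- function(config = generator_config(),
                                coordinates = TRUE) {
  truth <- simulate_states(config)
  if (coordinates) {
    em <- emit_coordinates(truth, config)
    c(list(truth = truth), em)
  } else {
    list(truth = truth, series = emit_series_only(truth, config))
  }
}
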