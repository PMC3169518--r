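# Per-frame progress variables: the R inter-strand distance parameter, the
# fraction of native sidechain contacts Q, Calpha RMSD to the native
# structure, and characteristic distance series.
#
# Distances are plain Euclidean distances in nm: inputs are assumed to be
# whole-molecule coordinates with no periodic-boundary wrapping (real MD
# input must be imaged onto the molecule before use).

# Aligned per-frame distance between one atom of residue i and one of j.
track_distance <- function(traj, res_i, atom_i, res_j, atom_j, idx) {
  a <- atom_track(traj, res_i, atom_i)
  b <- atom_track(traj, res_j, atom_j)
  if (nrow(a) != nrow(idx) || nrow(b) != nrow(idx)) {
    stop_hairpin(
      sprintf("atom %s of residue %d (or %s of %d) not present in every frame",
              atom_i, res_i, atom_j, res_j),
      "structure_error"
    )
  }
  euclid(a[, c("x", "y", "z")], b[, c("x", "y", "z")])
}

# Per-frame distance vector for a residue pair, aligned to frames_index(traj).
pair_distance_vec <- function(traj, res_i, res_j, mode, idx) {
  if (!all(c(res_i, res_j) %in% traj$residue_index)) {
    stop_hairpin(sprintf("unknown residue in pair (%d, %d)", res_i, res_j),
                 "structure_error")
  }
  if (mode == "calpha") {
    return(track_distance(traj, res_i, "CA", res_j, "CA", idx))
  }
  first <- traj[traj$frame == traj$frame[1] & traj$traj_id == traj$traj_id[1], ,
                drop = FALSE]
  first <- ensure_backbone_flag(first)
  set_i <- sidechain_atom_names(first, res_i)
  set_j <- sidechain_atom_names(first, res_j)
  combos <- expand.grid(ai = set_i, aj = set_j, stringsAsFactors = FALSE)
  d <- NULL
  for (k in seq_len(nrow(combos))) {
    dk <- track_distance(traj, res_i, combos$ai[k], res_j, combos$aj[k], idx)
    d <- if (is.null(d)) dk else pmin(d, dk)
  }
  d
}

#' Per-frame distance series for a residue pair
#'
#' Computes either the Calpha-Calpha distance or the minimum distance over
#' all cross pairs of sidechain heavy atoms (glycine represented by its
#' Calpha), for every frame of the trajectory.
#'
#' @param traj Trajectory tibble.
#' @param pair Integer vector of two residue indices, e.g. `c(6, 9)`.
#' @param mode `"calpha"` or `"sidechain_min"`.
#' @return Tibble with `traj_id`, `time_ps`, `distance_nm` and the pair as
#'   attributes `pair` and `mode`.
#' @export
compute_distance_series <- function(traj, pair, mode = c("calpha", "sidechain_min")) {
  mode <- match.arg(mode)
  validate_trajectory(traj)
  traj <- ensure_backbone_flag(traj)
  idx <- frames_index(traj)
  d <- pair_distance_vec(traj, as.integer(pair[1]), as.integer(pair[2]), mode, idx)
  out <- tibble(traj_id = idx$traj_id, time_ps = idx$time_ps, distance_nm = d)
  attr(out, "pair") <- as.integer(pair)
  attr(out, "mode") <- mode
  out
}

# Vectorized R over all frames.
r_series <- function(traj, ref, idx) {
  pairs <- ref$native_pair_distances
  total <- 0
  for (k in seq_len(nrow(pairs))) {
    d <- track_distance(traj, pairs$res_i[k], "CA", pairs$res_j[k], "CA", idx)
    if (any(d == 0)) {
      stop_hairpin("zero inter-strand distance in frame", "degenerate_geometry_error")
    }
    total <- total + pairs$distance_nm[k] / d
  }
  total
}

# Vectorized Q over all frames.
q_series <- function(traj, ref, contact_cutoff, idx) {
  contacts <- ref$native_contacts
  if (is.null(contacts) || nrow(contacts) == 0) {
    stop_hairpin("reference has an empty native contact list", "configuration_error")
  }
  formed <- 0
  for (k in seq_len(nrow(contacts))) {
    d <- pair_distance_vec(traj, contacts$res_i[k], contacts$res_j[k],
                           "sidechain_min", idx)
    formed <- formed + (d <= contact_cutoff)
  }
  formed / nrow(contacts)
}

# Matched Calpha coordinate matrices (frame rows ordered by residue match).
ca_matrix <- function(atoms, residues) {
  ca <- atoms[atoms$atom_name == "CA", , drop = FALSE]
  rows <- match(residues, ca$residue_index)
  if (anyNA(rows)) {
    stop_hairpin(paste0("missing CA for residue(s): ",
                        paste(residues[is.na(rows)], collapse = ", ")),
                 "structure_error")
  }
  as.matrix(ca[rows, c("x", "y", "z")])
}

rmsd_series <- function(traj, ref, idx, fit = TRUE) {
  residues <- sort(intersect(
    unique(ref$atoms$residue_index[ref$atoms$atom_name == "CA"]),
    unique(traj$residue_index[traj$atom_name == "CA"])
  ))
  if (length(residues) < 3) {
    stop_hairpin("need at least 3 shared CA atoms for RMSD", "structure_error")
  }
  a <- ca_matrix(ref$atoms, residues)
  if (fit) {
    centred <- sweep(a, 2, colMeans(a))
    if (qr(centred)$rank < 2) {
      stop_hairpin("reference CA set is collinear; superposition is degenerate",
                   "numerical_degeneracy_error")
    }
  }
  ca <- traj[traj$atom_name == "CA" & traj$residue_index %in% residues, , drop = FALSE]
  ca <- ca[order(ca$traj_id, ca$frame, match(ca$residue_index, residues)), , drop = FALSE]
  n_res <- length(residues)
  n_frames <- nrow(idx)
  if (nrow(ca) != n_res * n_frames) {
    stop_hairpin("CA atoms not present in every frame", "structure_error")
  }
  xyz <- matrix(t(as.matrix(ca[, c("x", "y", "z")])), nrow = n_frames,
                ncol = 3 * n_res, byrow = TRUE)
  if (!fit) {
    ref_vec <- as.numeric(t(a))
    sq <- sweep(xyz, 2, ref_vec)^2
    return(sqrt(rowSums(sq) / n_res))
  }
  as.numeric(bio3d::rmsd(a = as.numeric(t(a)), b = xyz, fit = TRUE))
}

#' R parameter of one frame
#'
#' Sum over the five native inter-strand Calpha pairs of the ratio between
#' the native distance and the distance in the frame. Equals the pair count
#' (5) in the native conformation and decreases as the strands separate.
#'
#' @param frame Atom tibble of one conformation.
#' @param ref A [build_reference()] object.
#' @return A single dimensionless value.
#' @export
compute_R <- function(frame, ref) {
  traj <- as_single_frame(frame)
  r_series(traj, ref, frames_index(traj))
}

#' Fraction of native sidechain contacts of one frame
#'
#' @inheritParams compute_R
#' @param contact_cutoff Contact cutoff on the minimum sidechain heavy-atom
#'   distance, nm.
#' @return Fraction in `[0, 1]`.
#' @export
compute_Q <- function(frame, ref, contact_cutoff = 0.55) {
  traj <- as_single_frame(frame)
  q_series(traj, ref, contact_cutoff, frames_index(traj))
}

#' Calpha RMSD of one frame to the native structure
#'
#' @inheritParams compute_R
#' @param fit If `TRUE` (default) the frame is optimally superposed on the
#'   reference (Kabsch rotation + translation) before the RMSD is taken.
#' @return RMSD in nm.
#' @export
compute_rmsd <- function(frame, ref, fit = TRUE) {
  traj <- as_single_frame(frame)
  rmsd_series(traj, ref, frames_index(traj), fit = fit)
}

as_single_frame <- function(frame) {
  frame <- ensure_backbone_flag(validate_atoms(frame))
  if (!"traj_id" %in% names(frame)) frame$traj_id <- "frame"
  if (!"frame" %in% names(frame)) frame$frame <- 1L
  if (!"time_ps" %in% names(frame)) frame$time_ps <- 0
  frame
}

#' Order-parameter series of a trajectory
#'
#' Computes, for every frame, the R parameter and the fraction of native
#' sidechain contacts Q (and optionally the Calpha RMSD to the reference),
#' returning one tidy row per frame.
#'
#' @param traj Trajectory tibble.
#' @param ref A [build_reference()] object.
#' @param contact_cutoff Sidechain contact cutoff for Q, nm.
#' @param include_rmsd Also compute the Calpha RMSD column `rmsd`.
#' @return Tibble with `traj_id`, `time_ps`, `R`, `Q` (and `rmsd`).
#' @export
compute_order_params <- function(traj, ref, contact_cutoff = 0.55,
                                 include_rmsd = FALSE) {
  validate_trajectory(traj)
  traj <- ensure_backbone_flag(traj)
  idx <- frames_index(traj)
  out <- tibble(
    traj_id = idx$traj_id,
    time_ps = idx$time_ps,
    R = r_series(traj, ref, idx),
    Q = q_series(traj, ref, contact_cutoff, idx)
  )
  if (include_rmsd) out$rmsd <- rmsd_series(traj, ref, idx, fit = TRUE)
  out
}
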