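# Internal helpers shared across modules.

# Ideal gas constant in kJ/(mol K); all free energies are kJ/mol.
R_GAS <- 0.008314

# The five native inter-strand Calpha pairs of the 15-residue hairpin
# (E2-T14, S3-V13, Y4-T12, I5-W11, N6-T10). Residue 4/12 is the "middle"
# pair, (6,9) the turn and (1,15) the end-to-end pair.
native_pairs <- function() {
  tibble(res_i = c(2L, 3L, 4L, 5L, 6L), res_j = c(14L, 13L, 12L, 11L, 10L))
}

#' Characteristic residue pairs of the hairpin
#'
#' Returns the residue-index pairs used throughout the structural analysis:
#' the turn (N6-G9), middle (Y4-T12) and end-to-end (S1-E15) Calpha pairs,
#' and the two tryptophan sidechain pairs W11-P7 and W11-G9.
#'
#' @return A tibble with columns `label`, `res_i`, `res_j`, `mode`.
#' @export
characteristic_pairs <- function() {
  tibble(
    label = c("turn", "middle", "end", "w11_p7", "w11_g9"),
    res_i = c(6L, 4L, 1L, 11L, 11L),
    res_j = c(9L, 12L, 15L, 7L, 9L),
    mode  = c("calpha", "calpha", "calpha", "sidechain_min", "sidechain_min")
  )
}

backbone_names <- c("N", "CA", "C", "O")

stop_hairpin <- function(msg, class) {
  abort(msg, class = c(paste0("hairpintse_", class), "hairpintse_error"))
}

# Frame = atom table with residue_index, residue_name, atom_name,
# is_backbone, x, y, z (nm). A trajectory adds traj_id, frame, time_ps.
validate_atoms <- function(atoms, what = "frame") {
  need <- c("residue_index", "residue_name", "atom_name", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) {
    stop_hairpin(
      paste0(what, " is missing column(s): ", paste(miss, collapse = ", ")),
      "structure_error"
    )
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop_hairpin("non-finite coordinates", "structure_error")
  }
  invisible(atoms)
}

validate_trajectory <- function(traj) {
  validate_atoms(traj, what = "trajectory")
  need <- c("traj_id", "frame", "time_ps")
  miss <- setdiff(need, names(traj))
  if (length(miss) > 0) {
    stop_hairpin(
      paste0("trajectory is missing column(s): ", paste(miss, collapse = ", ")),
      "structure_error"
    )
  }
  invisible(traj)
}

# is_backbone from atom names when the flag is absent.
ensure_backbone_flag <- function(atoms) {
  if (!"is_backbone" %in% names(atoms)) {
    atoms$is_backbone <- atoms$atom_name %in% backbone_names
  }
  atoms
}

# Sidechain atom rows of one residue; glycine (or any residue without
# non-backbone heavy atoms) falls back to its Calpha as proxy.
sidechain_rows <- function(atoms, res) {
  rows <- atoms[atoms$residue_index == res & !atoms$is_backbone, , drop = FALSE]
  if (nrow(rows) == 0) {
    rows <- atoms[atoms$residue_index == res & atoms$atom_name == "CA", , drop = FALSE]
  }
  if (nrow(rows) == 0) {
    stop_hairpin(paste0("residue ", res, " has no sidechain atoms and no CA"),
                 "structure_error")
  }
  rows
}

# Atom names usable as the sidechain set of `res` (constant across frames).
sidechain_atom_names <- function(atoms, res) {
  unique(sidechain_rows(atoms, res)$atom_name)
}

euclid <- function(a, b) {
  sqrt(rowSums((as.matrix(a) - as.matrix(b))^2))
}

# Per-frame coordinates of one named atom of one residue, aligned on
# (traj_id, frame). Errors if the atom is absent from any frame.
atom_track <- function(traj, res, atom) {
  rows <- traj[traj$residue_index == res & traj$atom_name == atom, , drop = FALSE]
  rows <- rows[order(rows$traj_id, rows$frame), , drop = FALSE]
  rows
}

frames_index <- function(traj) {
  idx <- dplyr::distinct(traj, .data$traj_id, .data$frame, .data$time_ps)
  idx[order(idx$traj_id, idx$frame), , drop = FALSE]
}

# Single frame of a trajectory as a plain atom table.
#' Extract one frame of a trajectory as an atom table
#'
#' @param traj Trajectory tibble.
#' @param which Frame index (as stored in the `frame` column). Defaults to
#'   the first frame.
#' @return Atom tibble (one row per atom) without trajectory columns.
#' @export
get_frame <- function(traj, which = NULL) {
  validate_trajectory(traj)
  which <- which %||% min(traj$frame)
  out <- traj[traj$frame == which, , drop = FALSE]
  if (nrow(out) == 0) stop_hairpin("no such frame", "structure_error")
  out$traj_id <- NULL
  out$frame <- NULL
  out$time_ps <- NULL
  as_tibble(out)
}

infer_frame_interval <- function(times) {
  d <- diff(sort(unique(times)))
  if (length(d) == 0) stop_hairpin("cannot infer frame interval from one time", "format_error")
  stats::median(d)
}
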