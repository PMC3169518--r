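# Independent oracles and tiny fixture builders, used across test files.

R_GAS_T <- function(temperature = 300) 0.008314 * temperature

# Brute-force TS excursion enumeration over a symbol string: scans the
# string directly, independent of the package's rle-based path.
enumerate_segments_oracle <- function(states) {
  n <- length(states)
  out <- list()
  i <- 1L
  while (i <= n) {
    if (states[i] == "TS") {
      j <- i
      while (j < n && states[j + 1L] == "TS") j <- j + 1L
      if (i > 1L && j < n) {
        out[[length(out) + 1L]] <- data.frame(
          origin = states[i - 1L], destination = states[j + 1L],
          start = i, end = j, n_frames = j - i + 1L,
          stringsAsFactors = FALSE
        )
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  if (length(out) == 0) {
    return(data.frame(origin = character(), destination = character(),
                      start = integer(), end = integer(),
                      n_frames = integer()))
  }
  do.call(rbind, out)
}

# Labels tibble from a plain state string, times 0, dt, 2dt, ...
labels_from_string <- function(states, dt = 10, traj_id = "t1") {
  tibble::tibble(traj_id = traj_id,
                 time_ps = (seq_along(states) - 1) * dt,
                 state = states)
}

# Minimal atom table: one CA per residue at the given coordinate matrix.
ca_only_frame <- function(xyz, residues = seq_len(nrow(xyz))) {
  tibble::tibble(
    residue_index = as.integer(residues), residue_name = "ALA",
    atom_name = "CA", is_backbone = TRUE,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3]
  )
}

# Brute-force fraction of native contacts: direct double loop over the
# contact list and all sidechain atom pairs.
brute_force_q <- function(frame, ref, cutoff = 0.55) {
  sc <- function(res) {
    rows <- frame[frame$residue_index == res & !frame$is_backbone, , drop = FALSE]
    if (nrow(rows) == 0) {
      rows <- frame[frame$residue_index == res & frame$atom_name == "CA", ,
                    drop = FALSE]
    }
    as.matrix(rows[, c("x", "y", "z")])
  }
  contacts <- ref$native_contacts
  formed <- 0
  for (k in seq_len(nrow(contacts))) {
    a <- sc(contacts$res_i[k]); b <- sc(contacts$res_j[k])
    dmin <- Inf
    for (p in seq_len(nrow(a))) for (q in seq_len(nrow(b))) {
      dmin <- min(dmin, sqrt(sum((a[p, ] - b[q, ])^2)))
    }
    if (dmin <= cutoff) formed <- formed + 1
  }
  formed / nrow(contacts)
}

# Rigid-body motion: rotation about z then x, plus translation.
rigid_move <- function(frame, angle_z = 0.7, angle_x = 0.3,
                       shift = c(1, -2, 3)) {
  rz <- matrix(c(cos(angle_z), sin(angle_z), 0,
                 -sin(angle_z), cos(angle_z), 0, 0, 0, 1), 3, 3)
  rx <- matrix(c(1, 0, 0, 0, cos(angle_x), sin(angle_x),
                 0, -sin(angle_x), cos(angle_x)), 3, 3)
  xyz <- as.matrix(frame[, c("x", "y", "z")]) %*% rz %*% rx
  frame$x <- xyz[, 1] + shift[1]
  frame$y <- xyz[, 2] + shift[2]
  frame$z <- xyz[, 3] + shift[3]
  frame
}

# Attach trajectory columns to a single atom table.
as_traj <- function(frame, traj_id = "t1", frame_no = 1L, time_ps = 0) {
  frame$traj_id <- traj_id
  frame$frame <- frame_no
  frame$time_ps <- time_ps
  frame
}
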