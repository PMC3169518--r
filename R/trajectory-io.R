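# Structure and trajectory input/output.
#
# Internally all coordinates are in nanometres; PDB files (Angstrom) are
# converted on read and write. A trajectory is a long tibble with one row
# per atom per frame and columns traj_id, frame, time_ps, residue_index,
# residue_name, atom_name, is_backbone, x, y, z.

#' Read a multi-model PDB file as a trajectory
#'
#' Each MODEL becomes one frame; frames are assigned times 0, dt, 2*dt, ...
#' Coordinates are converted from Angstrom to nanometres.
#'
#' @param path Path to a multi-model PDB file with identical atom ordering
#'   in every model.
#' @param frame_interval Time between consecutive models, ps.
#' @param traj_id Identifier stored in the `traj_id` column; defaults to the
#'   file name without extension.
#' @return A trajectory tibble.
#' @export
read_pdb_trajectory <- function(path, frame_interval = 10, traj_id = NULL) {
  if (!file.exists(path)) stop_hairpin(paste0("no such file: ", path), "format_error")
  pdb <- tryCatch(
    suppressWarnings(bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)),
    error = function(e) {
      stop_hairpin(paste0("failed to parse PDB: ", conditionMessage(e)), "format_error")
    }
  )
  xyz <- pdb$xyz
  if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
  n_models <- nrow(xyz)
  n_atoms <- nrow(pdb$atom)
  if (n_models == 0 || n_atoms == 0) {
    stop_hairpin("PDB file contains no models", "empty_input_error")
  }
  if (ncol(xyz) != 3 * n_atoms) {
    stop_hairpin("inconsistent atom counts between models", "format_error")
  }
  if (n_models < 2) {
    stop_hairpin("trajectory needs at least 2 models", "empty_input_error")
  }
  traj_id <- traj_id %||% sub("\\.[^.]*$", "", basename(path))
  atoms <- tibble(
    residue_index = as.integer(pdb$atom$resno),
    residue_name = pdb$atom$resid,
    atom_name = pdb$atom$elety
  )
  atoms$is_backbone <- atoms$atom_name %in% backbone_names
  ix <- seq_len(n_atoms)
  out <- purrr::map(seq_len(n_models), function(m) {
    fr <- atoms
    fr$x <- xyz[m, 3 * ix - 2] / 10
    fr$y <- xyz[m, 3 * ix - 1] / 10
    fr$z <- xyz[m, 3 * ix] / 10
    fr$traj_id <- traj_id
    fr$frame <- m
    fr$time_ps <- (m - 1) * frame_interval
    fr
  })
  out <- dplyr::bind_rows(out)
  out <- out[, c("traj_id", "frame", "time_ps", "residue_index", "residue_name",
                 "atom_name", "is_backbone", "x", "y", "z")]
  validate_trajectory(out)
  as_tibble(out)
}

#' Write a trajectory as a multi-model PDB file
#'
#' Coordinates are converted from nanometres to Angstrom. One MODEL record
#' is written per frame, in frame order.
#'
#' @param traj Trajectory tibble (or a single-frame atom table).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_pdb_trajectory <- function(traj, path) {
  if (!"frame" %in% names(traj)) {
    traj$frame <- 1L
    traj$time_ps <- 0
    if (!"traj_id" %in% names(traj)) traj$traj_id <- "frame"
  }
  validate_trajectory(traj)
  if (length(unique(traj$traj_id)) > 1) {
    stop_hairpin("write one trajectory per file (multiple traj_id values found)",
                 "format_error")
  }
  frames <- sort(unique(traj$frame))
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (k in seq_along(frames)) {
    fr <- traj[traj$frame == frames[k], , drop = FALSE]
    writeLines(sprintf("MODEL     %4d", k), con)
    lines <- sprintf(
      "ATOM  %5d %-4s %3s A%4d    %8.3f%8.3f%8.3f  1.00  0.00           %s",
      seq_len(nrow(fr)),
      ifelse(nchar(fr$atom_name) < 4, paste0(" ", fr$atom_name), fr$atom_name),
      fr$residue_name, fr$residue_index,
      fr$x * 10, fr$y * 10, fr$z * 10,
      substr(fr$atom_name, 1, 1)
    )
    writeLines(lines, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}

#' Build the native reference structure
#'
#' From a single (native) frame, records the five native inter-strand
#' Calpha distances used by the R parameter and derives the native
#' sidechain contact list: all residue pairs with sequence separation at
#' least `min_separation` whose minimum sidechain heavy-atom distance is
#' within `contact_cutoff`. Glycine, having no heavy sidechain atom, is
#' represented by its Calpha.
#'
#' @param frame Atom tibble of the native conformation (must contain a CA
#'   atom for residues 1-15).
#' @param contact_cutoff Sidechain contact cutoff, nm.
#' @param min_separation Minimum sequence separation |i - j| for a contact.
#' @return An object of class `hairpin_ref`: list with `atoms`,
#'   `native_pair_distances`, `native_contacts`, `contact_cutoff`,
#'   `min_separation`.
#' @export
build_reference <- function(frame, contact_cutoff = 0.55, min_separation = 3) {
  frame <- ensure_backbone_flag(validate_atoms(frame))
  residues <- sort(unique(frame$residue_index))
  ca <- frame[frame$atom_name == "CA", , drop = FALSE]
  pairs <- native_pairs()
  need <- sort(unique(c(pairs$res_i, pairs$res_j)))
  miss <- setdiff(need, ca$residue_index)
  if (length(miss) > 0) {
    stop_hairpin(paste0("missing CA for residue(s): ", paste(miss, collapse = ", ")),
                 "structure_error")
  }
  ca_xyz <- function(res) {
    unlist(ca[match(res, ca$residue_index), c("x", "y", "z")], use.names = FALSE)
  }
  pairs$distance_nm <- vapply(seq_len(nrow(pairs)), function(k) {
    sqrt(sum((ca_xyz(pairs$res_i[k]) - ca_xyz(pairs$res_j[k]))^2))
  }, numeric(1))
  if (any(pairs$distance_nm <= 0)) {
    stop_hairpin("degenerate native geometry: zero inter-strand distance",
                 "degenerate_geometry_error")
  }

  combos <- expand.grid(res_i = residues, res_j = residues)
  combos <- combos[combos$res_j - combos$res_i >= min_separation, , drop = FALSE]
  formed <- vapply(seq_len(nrow(combos)), function(k) {
    a <- sidechain_rows(frame, combos$res_i[k])
    b <- sidechain_rows(frame, combos$res_j[k])
    d <- outer(seq_len(nrow(a)), seq_len(nrow(b)), function(p, q) {
      sqrt((a$x[p] - b$x[q])^2 + (a$y[p] - b$y[q])^2 + (a$z[p] - b$z[q])^2)
    })
    min(d) <= contact_cutoff
  }, logical(1))
  contacts <- as_tibble(combos[formed, , drop = FALSE])

  structure(
    list(
      atoms = as_tibble(frame),
      native_pair_distances = as_tibble(pairs),
      native_contacts = contacts,
      contact_cutoff = contact_cutoff,
      min_separation = min_separation
    ),
    class = "hairpin_ref"
  )
}

#' @export
print.hairpin_ref <- function(x, ...) {
  cat("<hairpin_ref>\n")
  cat("  atoms:", nrow(x$atoms), "\n")
  cat("  native inter-strand CA distances (nm):\n")
  print(x$native_pair_distances, n = 5)
  cat("  native sidechain contacts:", nrow(x$native_contacts),
      sprintf("(cutoff %.2f nm, separation >= %d)\n",
              x$contact_cutoff, x$min_separation))
  invisible(x)
}

#' Serialize a reference structure summary as JSON
#'
#' @param ref A `hairpin_ref` object.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_reference_json <- function(ref, path) {
  jsonlite::write_json(
    list(
      native_pair_distances = ref$native_pair_distances,
      native_contacts = ref$native_contacts,
      contact_cutoff = ref$contact_cutoff,
      min_separation = ref$min_separation
    ),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Write / read an order-parameter series as CSV
#'
#' The file has a header `traj_id,time_ps,R,Q` with an optional `rmsd`
#' column; write followed by read reproduces the series to six decimals.
#'
#' @param series Order-parameter tibble.
#' @param path File path.
#' @return `read_series` returns the series tibble; `write_series` returns
#'   `path` invisibly.
#' @export
write_series <- function(series, path) {
  keep <- intersect(c("traj_id", "time_ps", "R", "Q", "rmsd"), names(series))
  readr::write_csv(series[, keep], path)
  invisible(path)
}

#' @rdname write_series
#' @export
read_series <- function(path) {
  if (!file.exists(path)) stop_hairpin(paste0("no such file: ", path), "format_error")
  first <- readr::read_lines(path, n_max = 1)
  cols <- strsplit(first, ",")[[1]]
  spec <- list(traj_id = readr::col_character(), time_ps = readr::col_double(),
               R = readr::col_double(), Q = readr::col_double(),
               rmsd = readr::col_double())
  unknown <- setdiff(cols, names(spec))
  if (length(unknown) > 0) {
    stop_hairpin(paste0("unknown series column(s): ", paste(unknown, collapse = ", ")),
                 "parse_error")
  }
  out <- suppressWarnings(
    readr::read_csv(path, col_types = do.call(readr::cols, spec[cols]),
                    progress = FALSE)
  )
  prob <- readr::problems(out)
  if (nrow(prob) > 0) {
    stop_hairpin(
      sprintf("malformed series row at line %d: expected %s, got '%s'",
              prob$row[1], prob$expected[1], prob$actual[1]),
      "parse_error"
    )
  }
  out
}
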