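# Structural characterization of ensembles: distance histograms of the
# TSE and F state, per-path-class TS subpopulations, the prior-to-TS
# ensemble, and distance time courses along reactive paths.

#' Distance histogram of a frame ensemble
#'
#' Normalized histogram (frequencies summing to 1) of a pair distance over
#' a selected set of frames, with the modal bin center reported as the
#' peak.
#'
#' @param traj Trajectory tibble.
#' @param frames Frame selector: tibble with `traj_id` and `time_ps`.
#' @param pair Residue pair, e.g. `c(1, 15)`.
#' @param mode `"calpha"` or `"sidechain_min"`.
#' @param bin_width Histogram bin width, nm (default 0.02).
#' @param label Optional ensemble label stored as an attribute.
#' @return Tibble with `bin_center`, `count`, `density`; attributes
#'   `peak_nm` (modal bin center), `n`, `pair`, `mode`, `label`.
#' @export
ensemble_histogram <- function(traj, frames, pair,
                               mode = c("calpha", "sidechain_min"),
                               bin_width = 0.02, label = NULL) {
  mode <- match.arg(mode)
  if (is.null(frames) || nrow(frames) == 0) {
    stop_hairpin("empty frame selector", "empty_ensemble_error")
  }
  ds <- compute_distance_series(traj, pair, mode)
  sel <- dplyr::semi_join(ds, frames, by = c("traj_id", "time_ps"))
  if (nrow(sel) == 0) {
    stop_hairpin("selector matches no frames of the trajectory",
                 "empty_ensemble_error")
  }
  distance_histogram(sel$distance_nm, bin_width, pair = pair, mode = mode,
                     label = label)
}

distance_histogram <- function(d, bin_width, pair = NULL, mode = NULL,
                               label = NULL) {
  lo <- floor(min(d) / bin_width) * bin_width
  idx <- pmax(floor((d - lo) / bin_width) + 1L, 1L)
  tab <- table(idx)
  bins <- as.integer(names(tab))
  out <- tibble(
    bin_center = lo + (bins - 0.5) * bin_width,
    count = as.numeric(tab)
  )
  out$density <- out$count / sum(out$count)
  attr(out, "peak_nm") <- out$bin_center[which.max(out$count)]
  attr(out, "n") <- length(d)
  attr(out, "pair") <- pair
  attr(out, "mode") <- mode
  attr(out, "label") <- label
  attr(out, "bin_width") <- bin_width
  out
}

#' Frames within a window before TS entry on forward reactive paths
#'
#' For every forward reactive (UTSF) excursion, selects the frames in
#' `[start - window, start)` of the same trajectory, clipped at the
#' trajectory start; frames already labelled TS or F are excluded, so the
#' selection is disjoint from the TSE by construction.
#'
#' @param labels State label tibble.
#' @param segments Segment tibble from [segment_paths()].
#' @param window Window length before TS entry, ps (default 1000).
#' @return Frame selector tibble (`traj_id`, `time_ps`), without
#'   duplicates.
#' @export
prior_to_ts_ensemble <- function(labels, segments, window = 1000) {
  if (window <= 0) stop_hairpin("window must be > 0", "configuration_error")
  fwd <- segments[segments$class == "UTSF", , drop = FALSE]
  if (nrow(fwd) == 0) {
    stop_hairpin("no forward reactive (UTSF) excursions", "empty_ensemble_error")
  }
  picks <- purrr::map(seq_len(nrow(fwd)), function(k) {
    lab <- labels[labels$traj_id == fwd$traj_id[k], , drop = FALSE]
    lab[lab$time_ps >= fwd$start_ps[k] - window &
        lab$time_ps < fwd$start_ps[k] &
        !(lab$state %in% c("TS", "F")), c("traj_id", "time_ps")]
  })
  dplyr::distinct(dplyr::bind_rows(picks))
}

# TS frames of each excursion as a selector with the excursion's class.
ts_frames_by_class <- function(segments, labels) {
  picks <- purrr::map(seq_len(nrow(segments)), function(k) {
    lab <- labels[labels$traj_id == segments$traj_id[k], , drop = FALSE]
    sel <- lab[lab$time_ps >= segments$start_ps[k] &
               lab$time_ps <= segments$end_ps[k], c("traj_id", "time_ps")]
    sel$class <- segments$class[k]
    sel
  })
  dplyr::bind_rows(picks)
}

#' Per-path-class TS distance distributions
#'
#' Pools the TS frames of each path class and computes the five
#' characteristic observables of the hairpin (turn, middle and end-to-end
#' Calpha distances, and the W11-P7 / W11-G9 minimum sidechain distances)
#' as normalized histograms. For the non-reactive FTSF class the fraction
#' of TS frames whose middle Calpha distance is within
#' `middle_formed_max` (i.e. with the middle backbone contacts formed, the
#' folding-nucleus signature) is also reported.
#'
#' @param segments Segment tibble from [segment_paths()].
#' @param traj Trajectory tibble.
#' @param labels State label tibble aligned with `traj`.
#' @param bin_width Histogram bin width, nm.
#' @param middle_formed_max Middle Calpha distance below which the middle
#'   backbone contacts count as formed, nm (default 0.6).
#' @return List with `histograms` (long tibble: `class`, `observable`,
#'   `bin_center`, `count`, `density`), `ftsf_nucleus_fraction` (`NA` when
#'   no FTSF excursions exist), `absent_classes`, and `n_frames` per class.
#' @export
subpopulation_histograms <- function(segments, traj, labels, bin_width = 0.02,
                                     middle_formed_max = 0.6) {
  obs <- characteristic_pairs()
  classes <- c("UTSF", "FTSU", "UTSU", "FTSF")
  present <- intersect(classes, unique(segments$class))
  if (length(present) == 0) {
    stop_hairpin("no TS excursions of any class", "empty_ensemble_error")
  }
  frames <- ts_frames_by_class(segments, labels)
  series <- purrr::map(seq_len(nrow(obs)), function(k) {
    ds <- compute_distance_series(traj, c(obs$res_i[k], obs$res_j[k]), obs$mode[k])
    ds$observable <- obs$label[k]
    ds
  })
  series <- dplyr::bind_rows(series)
  joined <- dplyr::inner_join(frames, series, by = c("traj_id", "time_ps"),
                              relationship = "many-to-many")
  hists <- list()
  for (cl in present) {
    for (ob in obs$label) {
      d <- joined$distance_nm[joined$class == cl & joined$observable == ob]
      if (length(d) == 0) next
      h <- distance_histogram(d, bin_width)
      h$class <- cl
      h$observable <- ob
      hists[[length(hists) + 1]] <- h
    }
  }
  ftsf_mid <- joined$distance_nm[joined$class == "FTSF" &
                                 joined$observable == "middle"]
  n_frames <- dplyr::count(dplyr::distinct(frames), .data$class, name = "n_frames")
  list(
    histograms = dplyr::bind_rows(hists),
    ftsf_nucleus_fraction = if (length(ftsf_mid))
      mean(ftsf_mid <= middle_formed_max) else NA_real_,
    absent_classes = setdiff(classes, present),
    n_frames = n_frames
  )
}

#' Distance time courses along forward reactive paths
#'
#' For every UTSF excursion, extracts aligned time series of the turn,
#' middle and end-to-end Calpha distances and the W11-P7 minimum sidechain
#' distance over `[start - window, end + window]` (clipped to the
#' trajectory), with the TS span annotated.
#'
#' @param segments Segment tibble from [segment_paths()].
#' @param traj Trajectory tibble.
#' @param window Padding before and after the TS span, ps.
#' @param observables Subset of `characteristic_pairs()$label` to extract.
#' @return Long tibble: `segment_id`, `traj_id`, `time_ps`, `observable`,
#'   `distance_nm`, `in_ts`.
#' @export
reactive_timecourse <- function(segments, traj, window = 1000,
                                observables = c("turn", "middle", "end", "w11_p7")) {
  fwd <- segments[segments$class == "UTSF", , drop = FALSE]
  if (nrow(fwd) == 0) {
    stop_hairpin("no forward reactive (UTSF) excursions", "empty_ensemble_error")
  }
  if (length(observables) == 0) {
    return(tibble(segment_id = integer(), traj_id = character(),
                  time_ps = numeric(), observable = character(),
                  distance_nm = numeric(), in_ts = logical()))
  }
  obs <- characteristic_pairs()
  obs <- obs[obs$label %in% observables, , drop = FALSE]
  series <- purrr::map(seq_len(nrow(obs)), function(k) {
    ds <- compute_distance_series(traj, c(obs$res_i[k], obs$res_j[k]), obs$mode[k])
    ds$observable <- obs$label[k]
    ds
  })
  series <- dplyr::bind_rows(series)
  out <- purrr::map(seq_len(nrow(fwd)), function(k) {
    sel <- series[series$traj_id == fwd$traj_id[k] &
                  series$time_ps >= fwd$start_ps[k] - window &
                  series$time_ps <= fwd$end_ps[k] + window, , drop = FALSE]
    sel$segment_id <- k
    sel$in_ts <- sel$time_ps >= fwd$start_ps[k] & sel$time_ps <= fwd$end_ps[k]
    sel
  })
  out <- dplyr::bind_rows(out)
  out[, c("segment_id", "traj_id", "time_ps", "observable", "distance_nm", "in_ts")]
}
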