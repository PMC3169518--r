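# TS excursion segmentation, path-scenario classification, and
# residence-time kinetics. Residence times are quantized at the frame
# interval: a run of k TS frames scores k * dt ps.

#' Segment state labels into TS excursions
#'
#' Every maximal TS run flanked on both sides by non-TS labels yields one
#' path segment with the preceding state as origin and the following state
#' as destination. TS runs touching a trajectory boundary are discarded
#' (their origin or destination is unknown).
#'
#' @param labels State label tibble (`traj_id`, `time_ps`, `state`).
#' @param frame_interval Frame spacing in ps; inferred from the time stamps
#'   when omitted.
#' @return Tibble with one row per excursion: `traj_id`, `origin`,
#'   `destination`, `class` (`"UTSF"`, `"FTSU"`, `"UTSU"`, `"FTSF"`),
#'   `start_ps`, `end_ps`, `n_frames`, `residence_ps`.
#' @export
segment_paths <- function(labels, frame_interval = NULL) {
  if (nrow(labels) == 0) stop_hairpin("empty label series", "empty_input_error")
  labels <- labels[order(labels$traj_id, labels$time_ps), , drop = FALSE]
  frame_interval <- frame_interval %||% infer_frame_interval(labels$time_ps)
  out <- list()
  for (id in unique(labels$traj_id)) {
    one <- labels[labels$traj_id == id, , drop = FALSE]
    runs <- state_runs(one)
    k <- which(runs$state == "TS")
    k <- k[k > 1 & k < nrow(runs)]
    if (length(k) == 0) next
    n <- runs$end[k] - runs$start[k] + 1L
    out[[length(out) + 1]] <- tibble(
      traj_id = id, origin = runs$state[k - 1], destination = runs$state[k + 1],
      class = paste0(runs$state[k - 1], "TS", runs$state[k + 1]),
      start_ps = one$time_ps[runs$start[k]],
      end_ps = one$time_ps[runs$end[k]],
      n_frames = n, residence_ps = n * frame_interval
    )
  }
  if (length(out) == 0) {
    return(tibble(traj_id = character(), origin = character(),
                  destination = character(), class = character(),
                  start_ps = numeric(), end_ps = numeric(),
                  n_frames = integer(), residence_ps = numeric()))
  }
  dplyr::bind_rows(out)
}

# Monoexponential fit A exp(-t/tau) to the residence-time histogram by
# iteratively reweighted least squares on the log-linearized counts with
# Poisson weights (stats::glm with log link). Zero-count bins inside the
# observed range are kept: dropping them biases the tail upward.
fit_exp_histogram <- function(residence_ps, frame_interval) {
  k <- round(residence_ps / frame_interval)
  if (length(unique(k)) < 2) {
    stop_hairpin("all residence times equal: degenerate histogram", "fit_error")
  }
  bins <- seq_len(max(k))
  count <- as.numeric(table(factor(k, levels = bins)))
  t <- bins * frame_interval
  fit <- suppressWarnings(stats::glm(count ~ t, family = stats::poisson()))
  slope <- unname(coef(fit)[2])
  if (!is.finite(slope) || slope >= 0) {
    stop_hairpin("residence histogram is not decaying", "fit_error")
  }
  tau <- -1 / slope
  amp <- exp(unname(coef(fit)[1]))
  fitted <- amp * exp(-t / tau)
  list(tau = tau, amplitude = amp,
       correlation = stats::cor(count, fitted),
       histogram = tibble(t_ps = t, count = count, fitted = fitted))
}

#' Fit the TS lifetime from excursion residence times
#'
#' The residence-time histogram (bin width = one frame interval) is fitted
#' by a monoexponential A exp(-t/tau) via weighted least squares on the
#' log-linearized bin counts with Poisson weights; the time constant is the
#' TS lifetime. The commitment fraction `p_fold` is the fraction of
#' excursions exiting to the folded state. The error on tau is the standard
#' error of the mean over `n_groups` disjoint trajectory subsets.
#' `method = "mle"` instead takes tau as the mean residence time (the
#' maximum-likelihood estimate for the discretized exponential).
#'
#' @param segments Segment tibble from [segment_paths()].
#' @param frame_interval Frame spacing, ps; inferred from the residence
#'   quantum when omitted.
#' @param n_groups Number of trajectory subsets for the error estimate.
#' @param method `"wls"` (histogram fit, default) or `"mle"`.
#' @param min_events Minimum number of excursions required (default 20).
#' @return Object of class `lifetime_fit` with elements `tau`, `tau_error`,
#'   `correlation`, `n_events`, `p_fold`, `p_unfold`, `histogram`, `method`.
#' @export
fit_lifetime <- function(segments, frame_interval = NULL, n_groups = 3,
                         method = c("wls", "mle"), min_events = 20) {
  method <- match.arg(method)
  if (nrow(segments) < min_events) {
    stop_hairpin(sprintf("only %d TS excursions; need at least %d",
                         nrow(segments), min_events),
                 "insufficient_events_error")
  }
  frame_interval <- frame_interval %||%
    (min(segments$residence_ps) / min(segments$n_frames))
  one_fit <- function(seg) {
    if (method == "wls") {
      fit_exp_histogram(seg$residence_ps, frame_interval)
    } else {
      list(tau = mean(seg$residence_ps), amplitude = NA_real_,
           correlation = NA_real_,
           histogram = {
             tab <- table(seg$residence_ps)
             tibble(t_ps = as.numeric(names(tab)), count = as.numeric(tab),
                    fitted = NA_real_)
           })
    }
  }
  main <- one_fit(segments)
  tau_error <- NA_real_
  if (!is.null(n_groups) && n_groups >= 2 &&
      length(unique(segments$traj_id)) >= n_groups) {
    grp <- default_groups(segments$traj_id, n_groups)
    taus <- vapply(sort(unique(grp)), function(g) {
      seg <- segments[grp[as.character(segments$traj_id)] == g, , drop = FALSE]
      tryCatch(one_fit(seg)$tau, error = function(e) NA_real_)
    }, numeric(1))
    if (!anyNA(taus)) tau_error <- stats::sd(taus) / sqrt(length(taus))
  }
  p_fold <- mean(segments$destination == "F")
  structure(
    list(tau = main$tau, tau_error = tau_error,
         correlation = main$correlation, n_events = nrow(segments),
         p_fold = p_fold, p_unfold = 1 - p_fold,
         amplitude = main$amplitude, histogram = main$histogram,
         method = method, frame_interval = frame_interval),
    class = "lifetime_fit"
  )
}

#' @export
print.lifetime_fit <- function(x, ...) {
  cat(sprintf("<lifetime_fit> tau = %.3g +/- %.3g ps (%s, %d excursions)\n",
              x$tau, x$tau_error, x$method, x$n_events))
  cat(sprintf("  fit correlation = %.4f; p_fold = %.3f, p_unfold = %.3f\n",
              x$correlation, x$p_fold, x$p_unfold))
  invisible(x)
}

#' Census of the four path scenarios
#'
#' Counts TS excursions per class (forward reactive UTSF, backward reactive
#' FTSU, and non-reactive UTSU / FTSF) with their mean residence times.
#'
#' @param segments Segment tibble from [segment_paths()].
#' @return Tibble with one row per class: `class`, `n`, `mean_residence_ps`
#'   and a logical `reactive` flag. Classes with no excursions appear with
#'   `n = 0` and `NA` mean residence.
#' @export
scenario_census <- function(segments) {
  classes <- c("UTSF", "FTSU", "UTSU", "FTSF")
  out <- purrr::map(classes, function(cl) {
    seg <- segments[segments$class == cl, , drop = FALSE]
    tibble(class = cl, n = nrow(seg),
           mean_residence_ps = if (nrow(seg)) mean(seg$residence_ps) else NA_real_,
           reactive = cl %in% c("UTSF", "FTSU"))
  })
  dplyr::bind_rows(out)
}
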