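# Orchestration: simulate (or ingest) -> order parameters -> landscape ->
# states -> path kinetics -> contact structure, with every intermediate
# written as a plain file and a JSON/markdown report.

#' Pipeline configuration
#'
#' Analysis defaults follow the study conditions: 40 x 40 grid, 300 K,
#' 0.55 nm contact cutoff, 12 kJ/mol basin cutoff, 3 error subsets, 1 ns
#' prior-to-TS window, 0.02 nm histogram bins.
#'
#' @param generator A [generator_config()] describing the input source.
#' @param mode `"geometry"` (full coordinate pipeline) or `"series"`
#'   (order-parameter fast path; skips the structural stages).
#' @param n_bins,temperature Landscape grid and temperature (K).
#' @param contact_cutoff Sidechain contact cutoff for Q, nm.
#' @param basin_cut Basin depth cutoff, kJ/mol.
#' @param n_groups Trajectory subsets for error estimates.
#' @param prior_window_ps Window of the prior-to-TS ensemble, ps.
#' @param bin_width Distance histogram bin width, nm.
#' @param middle_formed_max Middle-contact formation threshold, nm.
#' @param turn_native_max False-fold turn threshold, nm.
#' @param include_rmsd Also build the RMSD-Q landscape and report the TSE
#'   overlap between the two coordinate pairs (geometry mode only).
#' @param min_events Minimum excursions for the lifetime fit.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            mode = c("geometry", "series"),
                            n_bins = 40, temperature = 300,
                            contact_cutoff = 0.55, basin_cut = 12,
                            n_groups = 3, prior_window_ps = 1000,
                            bin_width = 0.02, middle_formed_max = 0.6,
                            turn_native_max = 0.8, include_rmsd = FALSE,
                            min_events = 20) {
  mode <- match.arg(mode)
  stopifnot(n_bins >= 2, temperature > 0, contact_cutoff > 0, basin_cut > 0,
            n_groups >= 2, prior_window_ps > 0, bin_width > 0)
  structure(
    list(generator = generator, mode = mode, n_bins = n_bins,
         temperature = temperature, contact_cutoff = contact_cutoff,
         basin_cut = basin_cut, n_groups = n_groups,
         prior_window_ps = prior_window_ps, bin_width = bin_width,
         middle_formed_max = middle_formed_max,
         turn_native_max = turn_native_max, include_rmsd = include_rmsd,
         min_events = min_events),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Simulates the input, computes order parameters, builds the free-energy
#' landscape with subset errors, decomposes it into U/TS/F, segments and
#' fits the TS kinetics, and (in geometry mode) characterizes the TSE
#' structurally. All randomness derives from the generator seed, so a
#' rerun with the same configuration reproduces the report exactly.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional directory; when given, every intermediate (CSV)
#'   and the report (JSON + markdown) are written there.
#' @return Object of class `tse_report` (a list of results).
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_hairpin(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                   "stage_error")
    })
  }
  gen <- config$generator
  geometry <- config$mode == "geometry"
  sim <- stage("simulate", simulate_trajectory(gen, coordinates = geometry))
  if (geometry) {
    series <- stage("order_parameters",
                    compute_order_params(sim$traj, sim$ref,
                                         contact_cutoff = config$contact_cutoff,
                                         include_rmsd = config$include_rmsd))
    turn_series <- stage("turn_series",
                         compute_distance_series(sim$traj, c(6, 9), "calpha"))
  } else {
    series <- sim$series
    turn_series <- NULL
  }
  grid <- stage("landscape",
                build_landscape(series, "Q", "R", config$n_bins,
                                config$temperature))
  if (gen$n_traj >= config$n_groups) {
    grid <- stage("subset_errors", subset_errors(grid, series, config$n_groups))
  }
  defn <- stage("find_basins", find_basins(grid, config$basin_cut))
  labels <- stage("assign_states", assign_states(series, grid, defn))
  exclusions <- NULL
  if (geometry) {
    refined <- stage("refine_tse",
                     refine_tse(labels, turn_series, config$turn_native_max))
    labels <- refined$labels
    exclusions <- refined$exclusions
  }
  segments <- stage("segment_paths", segment_paths(labels))
  fit <- tryCatch(
    fit_lifetime(segments, frame_interval = gen$frame_interval_ps,
                 n_groups = config$n_groups, min_events = config$min_events),
    error = function(e) NULL
  )
  census <- scenario_census(segments)

  modal <- NULL; subpop <- NULL; prior_n <- NA_integer_
  if (geometry) {
    obs <- characteristic_pairs()
    excl <- if ("tse_excluded" %in% names(labels)) labels$tse_excluded else FALSE
    tse_frames <- labels[labels$state == "TS" & !excl,
                         c("traj_id", "time_ps")]
    f_frames <- labels[labels$state == "F", c("traj_id", "time_ps")]
    modal <- purrr::map(seq_len(nrow(obs)), function(k) {
      per_ens <- purrr::map(list(TSE = tse_frames, F = f_frames), function(fr) {
        if (nrow(fr) == 0) return(NA_real_)
        h <- ensemble_histogram(sim$traj, fr, c(obs$res_i[k], obs$res_j[k]),
                                obs$mode[k], config$bin_width)
        attr(h, "peak_nm")
      })
      tibble(observable = obs$label[k], tse_peak_nm = per_ens$TSE,
             f_peak_nm = per_ens$F)
    })
    modal <- dplyr::bind_rows(modal)
    subpop <- tryCatch(
      subpopulation_histograms(segments, sim$traj, labels,
                               bin_width = config$bin_width,
                               middle_formed_max = config$middle_formed_max),
      error = function(e) NULL
    )
    prior_n <- tryCatch(
      nrow(prior_to_ts_ensemble(labels, segments, config$prior_window_ps)),
      error = function(e) NA_integer_
    )
  }
  overlap <- NULL
  if (geometry && config$include_rmsd) {
    overlap <- tryCatch({
      grid2 <- build_landscape(series, "Q", "rmsd", config$n_bins,
                               config$temperature)
      defn2 <- find_basins(grid2, config$basin_cut)
      labels2 <- assign_states(series, grid2, defn2)
      tse_overlap(labels, labels2)
    }, error = function(e) NULL)
  }

  centers_x <- axis_centers(grid$x_axis)
  centers_y <- axis_centers(grid$y_axis)
  basins <- tibble(
    state = c("F", "U"),
    Q = centers_x[c(defn$f_seed[1], defn$u_seed[1])],
    R = centers_y[c(defn$f_seed[2], defn$u_seed[2])],
    deltaA = c(
      grid$cells$deltaA[grid$cells$ix == defn$f_seed[1] & grid$cells$iy == defn$f_seed[2]],
      grid$cells$deltaA[grid$cells$ix == defn$u_seed[1] & grid$cells$iy == defn$u_seed[2]]
    )
  )
  report <- structure(
    list(config = config, basins = basins,
         n_frames = grid$n_frames,
         tse_size = sum(labels$state == "TS"),
         fit = fit, census = census,
         modal_distances = modal,
         ftsf_nucleus_fraction = if (!is.null(subpop)) subpop$ftsf_nucleus_fraction
                                 else NA_real_,
         prior_to_ts_n = prior_n,
         overlap = overlap,
         grid = grid, defn = defn, labels = labels, segments = segments,
         series = series, exclusions = exclusions),
    class = "tse_report"
  )
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' @export
print.tse_report <- function(x, ...) {
  cat("<tse_report>\n")
  cat(sprintf("  %d frames; TSE size %d frames\n", x$n_frames, x$tse_size))
  cat(sprintf("  basins: F at (Q = %.3f, R = %.3f); U at (Q = %.3f, R = %.3f, deltaA = %.2f kJ/mol)\n",
              x$basins$Q[1], x$basins$R[1], x$basins$Q[2], x$basins$R[2],
              x$basins$deltaA[2]))
  if (!is.null(x$fit)) {
    cat(sprintf("  TS lifetime tau = %.2f +/- %.2f ps (r = %.4f); p_fold = %.3f\n",
                x$fit$tau, x$fit$tau_error, x$fit$correlation, x$fit$p_fold))
  }
  print(x$census)
  invisible(x)
}

report_json_payload <- function(report) {
  list(
    basins = report$basins,
    n_frames = report$n_frames,
    tse_size = report$tse_size,
    lifetime = if (!is.null(report$fit)) {
      f <- report$fit
      list(tau_ps = f$tau, tau_error_ps = f$tau_error,
           correlation = f$correlation, n_events = f$n_events,
           p_fold = f$p_fold, p_unfold = f$p_unfold)
    },
    census = report$census,
    modal_distances = report$modal_distances,
    ftsf_nucleus_fraction = report$ftsf_nucleus_fraction,
    prior_to_ts_n = report$prior_to_ts_n,
    overlap = report$overlap,
    parameters = report$config[setdiff(names(report$config), "generator")],
    generator = report$config$generator[c("n_traj", "duration_us",
                                          "frame_interval_ps", "seed", "tau_u",
                                          "tau_ts", "tau_f", "p_fold",
                                          "ftsf_nucleus_fraction")]
  )
}

write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_series(report$series, file.path(out_dir, "series.csv"))
  write_landscape(report$grid, file.path(out_dir, "landscape.csv"))
  readr::write_csv(report$labels, file.path(out_dir, "labels.csv"))
  readr::write_csv(report$segments, file.path(out_dir, "segments.csv"))
  jsonlite::write_json(report_json_payload(report),
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  md <- c(
    "# Transition-state analysis report", "",
    sprintf("- frames analysed: %d", report$n_frames),
    sprintf("- TSE size: %d frames", report$tse_size),
    if (!is.null(report$fit))
      sprintf("- TS lifetime: %.2f +/- %.2f ps (fit r = %.4f)",
              report$fit$tau, report$fit$tau_error, report$fit$correlation),
    if (!is.null(report$fit))
      sprintf("- commitment: p_fold = %.3f, p_unfold = %.3f",
              report$fit$p_fold, report$fit$p_unfold),
    sprintf("- U basin depth: %.2f kJ/mol", report$basins$deltaA[2])
  )
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}
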