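# Ensemble histograms, prior-to-TS selection, subpopulations, timecourses.

sim_small <- local({
  cfg <- generator_config(n_traj = 3, duration_us = 0.04, seed = 37)
  sim <- simulate_trajectory(cfg, coordinates = TRUE)
  sim$labels <- dplyr::select(sim$truth$states, traj_id, time_ps, state)
  sim$segments <- segment_paths(sim$labels, frame_interval = 10)
  sim
})

test_that("histograms are normalized and place trivial masses correctly", {
  h <- hairpintse:::distance_histogram(rep(0.42, 50), 0.02)
  expect_equal(nrow(h), 1)
  expect_equal(h$density, 1)
  expect_lt(abs(attr(h, "peak_nm") - 0.42), 0.02)

  h2 <- hairpintse:::distance_histogram(c(0.3, 0.9), 0.02)
  expect_equal(sort(h2$density), c(0.5, 0.5))
  expect_equal(sum(h2$density), 1)

  expect_error(
    ensemble_histogram(sim_small$traj,
                       tibble::tibble(traj_id = character(),
                                      time_ps = numeric()),
                       c(1, 15)),
    class = "hairpintse_empty_ensemble_error"
  )
})

test_that("TSE and F ensembles peak at the imposed geometries", {
  lab <- sim_small$labels
  tse <- lab[lab$state == "TS", c("traj_id", "time_ps")]
  f <- lab[lab$state == "F", c("traj_id", "time_ps")]
  bw <- 0.02
  peaks <- function(frames, pair, mode = "calpha") {
    attr(ensemble_histogram(sim_small$traj, frames, pair, mode, bw), "peak_nm")
  }
  expect_lt(abs(peaks(tse, c(1, 15)) - 0.42), 2 * bw)
  expect_lt(abs(peaks(f, c(1, 15)) - 0.42), 2 * bw)
  expect_lt(abs(peaks(f, c(6, 9)) - 0.55), 2 * bw)
  expect_lt(abs(peaks(f, c(4, 12)) - 0.54), 2 * bw)
  # every ensemble histogram conserves mass
  h <- ensemble_histogram(sim_small$traj, tse, c(4, 12), "calpha", bw)
  expect_equal(sum(h$density), 1)
})

test_that("prior-to-TS window arithmetic, clipping and unions are exact", {
  states <- rep("U", 700)
  states[501:520] <- "TS"; states[521:700] <- "F"
  lab <- labels_from_string(states)  # TS entry at 5000 ps
  seg <- segment_paths(lab)
  prior <- prior_to_ts_ensemble(lab, seg, window = 1000)
  expect_equal(sort(prior$time_ps), seq(4000, 4990, by = 10))

  states2 <- c(rep("U", 30), "TS", rep("F", 20))  # entry at 300 ps
  lab2 <- labels_from_string(states2)
  prior2 <- prior_to_ts_ensemble(lab2, segment_paths(lab2), window = 1000)
  expect_equal(sort(prior2$time_ps), seq(0, 290, by = 10))

  # two UTSF excursions with overlapping windows: union without duplicates
  states3 <- c(rep("U", 40), "TS", rep("F", 3), rep("U", 20), "TS",
               rep("F", 10))
  lab3 <- labels_from_string(states3)
  seg3 <- segment_paths(lab3)
  prior3 <- prior_to_ts_ensemble(lab3, seg3, window = 1000)
  fwd <- seg3[seg3$class == "UTSF", ]
  expect_equal(nrow(fwd), 2)
  oracle_fwd <- sort(unique(unlist(
    purrr::map(seq_len(nrow(fwd)), function(k) {
      w <- seq(fwd$start_ps[k] - 1000, fwd$start_ps[k] - 10, by = 10)
      w <- w[w >= 0]
      w[states3[w / 10 + 1] == "U"]
    }))))
  expect_equal(sort(prior3$time_ps), oracle_fwd)
  expect_true(all(!duplicated(prior3[, c("traj_id", "time_ps")])))

  # the prior ensemble never intersects the TSE
  prior_big <- prior_to_ts_ensemble(sim_small$labels, sim_small$segments, 1000)
  tse <- sim_small$labels[sim_small$labels$state == "TS", ]
  expect_equal(nrow(dplyr::semi_join(prior_big, tse,
                                     by = c("traj_id", "time_ps"))), 0)
})

test_that("subpopulation histograms pool TS frames by class", {
  sub <- subpopulation_histograms(sim_small$segments, sim_small$traj,
                                  sim_small$labels)
  expect_true(all(sub$histograms |>
                    dplyr::group_by(class, observable) |>
                    dplyr::summarise(s = sum(density), .groups = "drop") |>
                    dplyr::pull(s) - 1 < 1e-12))
  # nucleus fraction near the configured 65%
  ftsf <- sim_small$segments[sim_small$segments$class == "FTSF", ]
  n <- nrow(ftsf)
  expect_gt(n, 30)
  expect_lt(abs(sub$ftsf_nucleus_fraction - 0.65), 3 * sqrt(0.65 * 0.35 / n))

  # a single UTSF segment yields a histogram over exactly its TS frames
  one <- sim_small$segments[sim_small$segments$class == "UTSF", ][1, ]
  sub1 <- subpopulation_histograms(one, sim_small$traj, sim_small$labels)
  n_utsf <- sum(sub1$histograms$count[sub1$histograms$class == "UTSF" &
                                      sub1$histograms$observable == "end"])
  expect_equal(n_utsf, one$n_frames)
  expect_setequal(sub1$absent_classes, c("FTSU", "UTSU", "FTSF"))
})

test_that("reactive timecourses span the requested windows", {
  tc0 <- reactive_timecourse(sim_small$segments, sim_small$traj, window = 0,
                             observables = "end")
  one <- sim_small$segments[sim_small$segments$class == "UTSF", ][1, ]
  tc_one <- tc0[tc0$segment_id == 1, ]
  expect_equal(range(tc_one$time_ps), c(one$start_ps, one$end_ps))
  expect_true(all(tc0$in_ts))

  empty <- reactive_timecourse(sim_small$segments, sim_small$traj,
                               observables = character(0))
  expect_equal(nrow(empty), 0)

  # mechanism: in the unfolded approach before the TS the turn is formed
  # while the ends are still apart
  tc <- reactive_timecourse(sim_small$segments, sim_small$traj, window = 1000)
  ts_start <- tc |>
    dplyr::filter(in_ts) |>
    dplyr::group_by(segment_id) |>
    dplyr::summarise(ts_entry = min(time_ps), .groups = "drop")
  pre <- tc |>
    dplyr::inner_join(ts_start, by = "segment_id") |>
    dplyr::filter(time_ps < ts_entry) |>
    dplyr::inner_join(sim_small$labels, by = c("traj_id", "time_ps")) |>
    dplyr::filter(state == "U")
  expect_gte(mean(pre$distance_nm[pre$observable == "turn"] < 0.8), 0.8)
  expect_gte(mean(pre$distance_nm[pre$observable == "end"] > 0.8), 0.8)
})
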