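# Generator ground truth: kinetics, templates, emission.

test_that("the generator is deterministic under a fixed seed", {
  cfg <- generator_config(n_traj = 2, duration_us = 0.005, seed = 123)
  t1 <- simulate_states(cfg)
  t2 <- simulate_states(cfg)
  expect_identical(t1$states, t2$states)
  expect_identical(t1$excursions, t2$excursions)
  expect_identical(emit_series_only(t1, cfg), emit_series_only(t2, cfg))
  e1 <- emit_coordinates(t1, cfg)
  e2 <- emit_coordinates(t2, cfg)
  expect_identical(e1$traj, e2$traj)
})

test_that("TS residences are geometric with the configured mean", {
  # tau_TS = 10 ps at 10 ps frames: escape probability 0.98, mean
  # residence 1/0.98 frames
  cfg <- generator_config(n_traj = 1, duration_us = 2.5, tau_ts = 10,
                          tau_u = 100, tau_f = 100, seed = 5)
  truth <- simulate_states(cfg)
  expect_gt(nrow(truth$excursions), 1e4)
  complete <- truth$excursions[!is.na(truth$excursions$class), ]
  expect_lt(abs(mean(complete$n_frames) - 1 / 0.98) / (1 / 0.98), 0.05)
})

test_that("branching limits and resolution guards hold", {
  cfg <- generator_config(n_traj = 1, duration_us = 0.05, p_fold = 1, seed = 2)
  truth <- simulate_states(cfg)
  classes <- truth$excursions$class[!is.na(truth$excursions$class)]
  expect_false(any(classes %in% c("UTSU", "FTSU")))
  expect_error(
    simulate_states(generator_config(tau_ts = 5, frame_interval_ps = 10)),
    class = "hairpintse_resolution_error"
  )
})

test_that("noiseless templates hit their geometric targets exactly", {
  cfg <- generator_config()
  native <- build_state_template(cfg, "F")
  ref <- build_reference(native)
  expect_identical(compute_R(native, ref), 5)
  expect_identical(compute_Q(native, ref), 1)

  d <- function(t, p, m = "calpha") {
    compute_distance_series(as_traj(t), p, m)$distance_nm
  }
  ts <- build_state_template(cfg, "TS")
  expect_equal(d(ts, c(1, 15)), 0.42, tolerance = 0.01)
  expect_equal(d(ts, c(6, 9)), 0.60, tolerance = 0.01)
  expect_equal(d(ts, c(4, 12)), 0.72, tolerance = 0.01)
  expect_equal(d(ts, c(11, 7), "sidechain_min"), 0.55, tolerance = 0.01)
  expect_equal(d(ts, c(11, 9), "sidechain_min"), 0.55, tolerance = 0.01)
  expect_equal(d(native, c(6, 9)), 0.55, tolerance = 0.01)
  expect_equal(d(native, c(4, 12)), 0.54, tolerance = 0.01)
  expect_equal(d(native, c(1, 15)), 0.42, tolerance = 0.01)

  u <- build_state_template(cfg, "U")
  r_u <- compute_R(u, ref)
  expect_gt(r_u, 1.8); expect_lt(r_u, 2.4)

  nucleus <- build_state_template(cfg, "nucleus")
  expect_lte(d(nucleus, c(4, 12)), 0.6)  # middle contacts formed
  expect_equal(d(nucleus, c(11, 7), "sidechain_min"), 0.30, tolerance = 0.01)
})

test_that("the fast-path emission concentrates at the basin centres", {
  cfg <- generator_config(n_traj = 2, duration_us = 0.05, seed = 13)
  truth <- simulate_states(cfg)
  # sigma -> 0: every frame lands in its state's centre cell
  cfg0 <- cfg
  cfg0$series$sd_q <- 1e-12
  cfg0$series$sd_r <- 1e-12
  s0 <- emit_series_only(truth, cfg0)
  expect_equal(nrow(dplyr::distinct(s0, round(Q, 6), round(R, 6))), 3)
  em <- cfg$series
  key <- paste(round(s0$Q, 3), round(s0$R, 3))
  want <- paste(round(em$mu_q[match(truth$states$state, em$state)], 3),
                round(em$mu_r[match(truth$states$state, em$state)], 3))
  expect_identical(key, want)

  # with default noise the landscape minima sit in the centre cells
  s <- emit_series_only(truth, cfg)
  grid <- build_landscape(s)
  defn <- find_basins(grid)
  cq <- hairpintse:::axis_centers(grid$x_axis)
  cr <- hairpintse:::axis_centers(grid$y_axis)
  expect_lt(abs(cq[defn$f_seed[1]] - 0.85), grid$x_axis$width)
  expect_lt(abs(cr[defn$f_seed[2]] - 4.95), grid$y_axis$width)
})

test_that("realized occupancy matches the analytic stationary distribution", {
  cfg <- generator_config(n_traj = 4, duration_us = 0.25, seed = 19)
  truth <- simulate_states(cfg)
  occ <- prop.table(table(truth$states$state))
  stat <- truth$stationary
  n_soj <- 2 * nrow(truth$excursions)  # sojourn count governs the precision
  for (st in stat$state) {
    p <- stat$occupancy[stat$state == st]
    expect_lt(abs(occ[[st]] - p), 3 * sqrt(p * (1 - p) / n_soj) + 0.01)
  }
})

test_that("coordinates encode the turn-first mechanism before TS entry", {
  cfg <- generator_config(n_traj = 2, duration_us = 0.05, seed = 23)
  sim <- simulate_trajectory(cfg, coordinates = TRUE)
  labels <- dplyr::select(sim$truth$states, traj_id, time_ps, state)
  seg <- segment_paths(labels, frame_interval = 10)
  prior <- prior_to_ts_ensemble(labels, seg, window = 1000)
  turn <- compute_distance_series(sim$traj, c(6, 9), "calpha")
  ends <- compute_distance_series(sim$traj, c(1, 15), "calpha")
  turn_prior <- dplyr::semi_join(turn, prior, by = c("traj_id", "time_ps"))
  ends_prior <- dplyr::semi_join(ends, prior, by = c("traj_id", "time_ps"))
  expect_gte(mean(turn_prior$distance_nm < 0.8), 0.8)
  expect_gte(mean(ends_prior$distance_nm > 0.8), 0.8)
})

test_that("FTSF excursions adopt the nucleus geometry at the configured rate", {
  cfg <- generator_config(n_traj = 4, duration_us = 0.1, seed = 29,
                          ftsf_nucleus_fraction = 0.65)
  truth <- simulate_states(cfg)
  ftsf <- truth$excursions[!is.na(truth$excursions$class) &
                           truth$excursions$class == "FTSF", ]
  n <- nrow(ftsf)
  expect_gt(n, 100)
  expect_lt(abs(mean(ftsf$nucleus) - 0.65), 3 * sqrt(0.65 * 0.35 / n))
})
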