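# Path segmentation, scenario census and lifetime fitting.

test_that("segment_paths reads excursions off the label string", {
  seg <- segment_paths(labels_from_string(c("U", "U", "TS", "TS", "F")))
  expect_equal(nrow(seg), 1)
  expect_equal(seg$class, "UTSF")
  expect_equal(seg$n_frames, 2L)
  expect_equal(seg$residence_ps, 20)

  seg2 <- segment_paths(labels_from_string(c("F", "TS", "F", "TS", "U")))
  expect_equal(seg2$class, c("FTSF", "FTSU"))
  expect_equal(seg2$n_frames, c(1L, 1L))

  # boundary TS runs are discarded
  expect_equal(nrow(segment_paths(labels_from_string(c("TS", "TS", "U")))), 0)
  expect_equal(nrow(segment_paths(labels_from_string(c("U", "F", "TS")))), 0)
})

test_that("segment_paths equals brute-force enumeration on random strings", {
  set.seed(99)
  n_strings <- 500
  lens <- sample(3:50, n_strings, replace = TRUE)
  all_labels <- purrr::map(seq_len(n_strings), function(k) {
    labels_from_string(sample(c("U", "TS", "F"), lens[k], replace = TRUE),
                       traj_id = sprintf("s%04d", k))
  })
  seg <- segment_paths(dplyr::bind_rows(all_labels))
  for (k in seq_len(n_strings)) {
    id <- sprintf("s%04d", k)
    mine <- seg[seg$traj_id == id, ]
    oracle <- enumerate_segments_oracle(all_labels[[k]]$state)
    expect_equal(nrow(mine), nrow(oracle))
    if (nrow(oracle) > 0) {
      expect_equal(mine$origin, oracle$origin)
      expect_equal(mine$destination, oracle$destination)
      expect_equal(mine$n_frames, oracle$n_frames)
      expect_equal(mine$start_ps, (oracle$start - 1) * 10)
    }
  }
})

test_that("the monoexponential fit recovers a known geometric lifetime", {
  # independent sampling oracle: residences drawn straight from the
  # geometric law with mean 10 ps at 1 ps resolution
  set.seed(7)
  dt <- 1
  n <- 5000
  k <- 1L + rgeom(n, dt / 10)
  seg <- tibble::tibble(
    traj_id = rep(sprintf("t%d", 1:5), length.out = n),
    origin = "U", destination = sample(c("F", "U"), n, TRUE),
    class = "x", start_ps = 0, end_ps = 0,
    n_frames = k, residence_ps = k * dt
  )
  fit <- fit_lifetime(seg, frame_interval = dt, n_groups = 3)
  expect_lt(abs(fit$tau - 10) / 10, 0.1)
  expect_gt(fit$correlation, 0.99)
  # the mean-residence estimate is the discrete MLE
  fit_mle <- fit_lifetime(seg, frame_interval = dt, method = "mle")
  expect_equal(fit_mle$tau, mean(seg$residence_ps))
})

test_that("lifetime recovery holds across tau = 5, 10, 20 ps", {
  for (tau in c(5, 10, 20)) {
    cfg <- generator_config(
      n_traj = 6, duration_us = 2000 * (50 + tau) / 6 * 1e-6,
      frame_interval_ps = 0.25, tau_u = 50, tau_f = 50, tau_ts = tau,
      p_fold = 0.5, seed = 100 + tau
    )
    truth <- simulate_states(cfg)
    labels <- dplyr::select(truth$states, traj_id, time_ps, state)
    seg <- segment_paths(labels, frame_interval = 0.25)
    expect_gt(nrow(seg), 1000)
    fit <- fit_lifetime(seg, frame_interval = 0.25, n_groups = 3)
    expect_lt(abs(fit$tau - tau) / tau, 0.1)
    # the error itself comes from only three subsets (sd with 2 degrees of
    # freedom), so it can by chance be near zero; floor the band at half
    # the recovery tolerance
    expect_lt(abs(fit$tau - tau), max(2 * fit$tau_error, 0.05 * tau))
    # mean residence of an exponential equals its time constant
    expect_lt(abs(mean(seg$residence_ps) - tau) / tau, 0.1)
  }
})

test_that("p_fold counts destinations and small samples are rejected", {
  seg <- dplyr::bind_rows(purrr::map(1:4, function(k) {
    n <- c(1L, 1L, 1L, 2L)[k]
    tibble::tibble(traj_id = "t1", origin = "U",
                   destination = c("F", "F", "F", "U")[k],
                   class = paste0("UTS", c("F", "F", "F", "U")[k]),
                   start_ps = k * 100, end_ps = k * 100 + 10 * n,
                   n_frames = n, residence_ps = n * 10)
  }))
  fit <- fit_lifetime(seg, frame_interval = 10, n_groups = NULL, min_events = 1)
  expect_equal(fit$p_fold, 0.75)
  expect_equal(fit$p_unfold, 0.25)
  ten <- dplyr::bind_rows(rep(list(seg), 3))[1:10, ]
  expect_error(fit_lifetime(ten, frame_interval = 10),
               class = "hairpintse_insufficient_events_error")
})

test_that("scenario census counts every class and is consistent with p_fold", {
  seg <- segment_paths(labels_from_string(c("F", "TS", "F", "TS", "U")))
  census <- scenario_census(seg)
  expect_equal(census$n[census$class == "FTSF"], 1L)
  expect_equal(census$n[census$class == "FTSU"], 1L)
  expect_equal(census$n[census$class == "UTSF"], 0L)
  expect_equal(census$n[census$class == "UTSU"], 0L)
  empty <- scenario_census(seg[0, ])
  expect_equal(empty$n, rep(0L, 4))
  expect_true(all(is.na(empty$mean_residence_ps)))

  # generator with 50/50 branching: UTSF vs UTSU counts within 3 sigma
  cfg <- generator_config(n_traj = 4, duration_us = 0.05, frame_interval_ps = 1,
                          tau_u = 50, tau_f = 50, tau_ts = 10, p_fold = 0.5,
                          seed = 17)
  truth <- simulate_states(cfg)
  seg2 <- segment_paths(dplyr::select(truth$states, traj_id, time_ps, state),
                        frame_interval = 1)
  census2 <- scenario_census(seg2)
  expect_equal(sum(census2$n), nrow(seg2))
  n_u_origin <- sum(seg2$origin == "U")
  n_utsf <- census2$n[census2$class == "UTSF"]
  expect_lt(abs(n_utsf - 0.5 * n_u_origin), 3 * sqrt(n_u_origin * 0.25))
  # definitional consistency: destination-F fraction equals p_fold
  fit <- fit_lifetime(seg2, frame_interval = 1)
  expect_equal(fit$p_fold, mean(seg2$destination == "F"))
})
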