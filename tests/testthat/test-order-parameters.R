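# R parameter, Q, RMSD and distance series.

cfg <- generator_config()
native <- build_state_template(cfg, "F")
ref <- build_reference(native)

test_that("R equals the pair count on the native structure and scales with distance", {
  expect_equal(compute_R(native, ref), 5)
  # uniform scaling about the origin doubles every distance: each ratio 0.5
  doubled <- native
  doubled[, c("x", "y", "z")] <- doubled[, c("x", "y", "z")] * 2
  expect_equal(compute_R(doubled, ref), 2.5)
})

test_that("R equals the hand-computed sum for prescribed distance ratios", {
  ratios <- c(1.0, 0.8, 0.5, 0.4, 0.25)
  pairs <- ref$native_pair_distances
  # dumbbell construction: each pair isolated on its own y level at the
  # distance native / ratio, so the ratio sum is known exactly
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    d <- pairs$distance_nm[k] / ratios[k]
    rows[[k]] <- ca_only_frame(
      rbind(c(0, 10 * k, 0), c(d, 10 * k, 0)),
      residues = c(pairs$res_i[k], pairs$res_j[k])
    )
  }
  frame <- dplyr::bind_rows(rows)
  expect_equal(compute_R(frame, ref), 2.95, tolerance = 1e-12)
})

test_that("R is invariant under rigid-body motion and rejects degenerate frames", {
  moved <- rigid_move(native)
  expect_equal(compute_R(moved, ref), 5, tolerance = 1e-9)
  collapsed <- native
  collapsed$x[collapsed$residue_index == 10 & collapsed$atom_name == "CA"] <-
    collapsed$x[collapsed$residue_index == 6 & collapsed$atom_name == "CA"]
  collapsed$y[collapsed$residue_index == 10 & collapsed$atom_name == "CA"] <-
    collapsed$y[collapsed$residue_index == 6 & collapsed$atom_name == "CA"]
  collapsed$z[collapsed$residue_index == 10 & collapsed$atom_name == "CA"] <-
    collapsed$z[collapsed$residue_index == 6 & collapsed$atom_name == "CA"]
  expect_error(compute_R(collapsed, ref),
               class = "hairpintse_degenerate_geometry_error")
})

test_that("Q is 1 in the native state, 0 in the open chain, and matches brute force", {
  expect_equal(compute_Q(native, ref), 1)
  expect_equal(compute_Q(build_state_template(cfg, "U"), ref), 0)
  # displace the sidechains of residues 10-12 far away: breaks exactly the
  # (6,10), (5,11), (4,12) contacts of the 6-contact ladder
  half <- native
  hit <- half$residue_index %in% 10:12 & !half$is_backbone
  half$z[hit] <- half$z[hit] + 10
  expect_equal(compute_Q(half, ref), 0.5)
  expect_equal(compute_Q(half, ref), brute_force_q(half, ref))
  ts <- build_state_template(cfg, "TS")
  expect_equal(compute_Q(ts, ref), brute_force_q(ts, ref))
})

test_that("Q is monotone non-increasing as the cutoff shrinks", {
  ts <- build_state_template(cfg, "TS")
  cutoffs <- seq(0.8, 0.3, by = -0.05)
  qs <- vapply(cutoffs, function(cc) compute_Q(ts, ref, cc), numeric(1))
  expect_true(all(diff(qs) <= 0))
  expect_error(
    compute_Q(native, build_reference(build_state_template(cfg, "U"))),
    class = "hairpintse_configuration_error"
  )
})

test_that("RMSD is zero under rigid motion and closed-form without superposition", {
  expect_equal(compute_rmsd(native, ref), 0, tolerance = 1e-9)
  expect_equal(compute_rmsd(rigid_move(native), ref), 0, tolerance = 1e-9)
  displaced <- native
  pick <- displaced$residue_index == 8 & displaced$atom_name == "CA"
  displaced$x[pick] <- displaced$x[pick] + 0.3
  expect_equal(compute_rmsd(displaced, ref, fit = FALSE), 0.3 / sqrt(15),
               tolerance = 1e-12)
  line <- ca_only_frame(cbind(seq(0, 1.4, 0.1), 0, 0))
  line_ref <- build_reference(build_state_template(cfg, "F"))
  line_ref$atoms <- line
  expect_error(compute_rmsd(line, line_ref),
               class = "hairpintse_numerical_degeneracy_error")
})

test_that("distance series match brute force and ignore irrelevant atoms", {
  # two single-atom sidechains 0.3 nm apart
  fr <- tibble::tibble(
    residue_index = c(1L, 1L, 5L, 5L), residue_name = "ALA",
    atom_name = c("CA", "CB", "CA", "CB"),
    is_backbone = c(TRUE, FALSE, TRUE, FALSE),
    x = 0, y = 0, z = c(0, 0, 1, 0.3)
  )
  ds <- compute_distance_series(as_traj(fr), c(1, 5), "sidechain_min")
  expect_equal(ds$distance_nm, 0.3)

  # 2x2 sidechain atoms: equals the exhaustive minimum over 4 distances
  set.seed(1)
  a <- matrix(rnorm(6), 2); b <- matrix(rnorm(6) + 1, 2)
  fr2 <- tibble::tibble(
    residue_index = c(1L, 1L, 1L, 6L, 6L, 6L), residue_name = "XXX",
    atom_name = c("CA", "CB", "CG", "CA", "CB", "CG"),
    is_backbone = c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE),
    x = c(9, a[, 1], 9, b[, 1]), y = c(9, a[, 2], 9, b[, 2]),
    z = c(9, a[, 3], 9, b[, 3])
  )
  brute <- min(as.vector(outer(1:2, 1:2, Vectorize(function(p, q) {
    sqrt(sum((a[p, ] - b[q, ])^2))
  }))))
  ds2 <- compute_distance_series(as_traj(fr2), c(1, 6), "sidechain_min")
  expect_equal(ds2$distance_nm, brute)

  # calpha mode is blind to sidechain perturbations
  perturbed <- native
  perturbed$z[!perturbed$is_backbone] <- perturbed$z[!perturbed$is_backbone] + 5
  d_native <- compute_distance_series(as_traj(native), c(6, 9), "calpha")
  d_pert <- compute_distance_series(as_traj(perturbed), c(6, 9), "calpha")
  expect_equal(d_pert$distance_nm, d_native$distance_nm)
  expect_error(compute_distance_series(as_traj(native), c(6, 99), "calpha"),
               class = "hairpintse_structure_error")
})
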