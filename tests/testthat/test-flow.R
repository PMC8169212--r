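test_that("plane Poiseuille flow matches the closed form", {
  lab <- make_channel_fixture("plane_slab", dims = c(8, 48, 16),
                              radius_or_gap = 32, voxel_size_um = 2)
  f <- solve_stokes(flow_problem(lab, "x", pressure_drop = 10))
  expect_true(f$percolating)
  h <- 2; gap <- 32 * h; H <- 48 * h
  k_true <- (gap / H) * gap^2 / 12
  expect_lt(abs(permeability(f) / k_true - 1), 0.05)
  # parabolic profile: max/mean -> 1.5
  d <- dim(f$fluid)
  uc <- (f$u[, , 1:d[3]] + f$u[, , 2:(d[3] + 1)]) / 2
  prof <- uc[4, , 8]
  prof <- prof[prof > 0]
  expect_lt(abs(max(prof) / mean(prof) - 1.5), 0.03 * 1.5)
  # discrete mass conservation
  expect_lt(abs(f$Q_in - f$Q_out) / abs(f$Q_in), 1e-6)
  expect_lt(f$div_rel_max, 1e-6)
})

test_that("Stokes flow is linear in the pressure drop", {
  lab <- make_channel_fixture("plane_slab", dims = c(6, 24, 12),
                              radius_or_gap = 12, voxel_size_um = 2)
  k1 <- permeability(solve_stokes(flow_problem(lab, "x", pressure_drop = 5)))
  k2 <- permeability(solve_stokes(flow_problem(lab, "x", pressure_drop = 10)))
  k10 <- permeability(solve_stokes(flow_problem(lab, "x", pressure_drop = 50)))
  expect_lt(abs(k2 / k1 - 1), 1e-3)
  expect_lt(abs(k10 / k1 - 1), 1e-3)
})

test_that("circular tube permeability matches Hagen-Poiseuille", {
  h <- 2; R <- 10.5
  n <- 28
  tb <- make_channel_fixture("circular_tube", dims = c(n, n, 10),
                             radius_or_gap = R, voxel_size_um = h)
  f <- solve_stokes(flow_problem(tb, "x", pressure_drop = 5))
  k_true <- pi * (R * h)^4 / (8 * n * n * h^2)
  expect_lt(abs(permeability(f) / k_true - 1), 0.10)
})

test_that("a blocked box yields zero flux and a non-percolating flag", {
  bb <- make_channel_fixture("blocked_box", dims = c(10, 10, 14))
  f <- solve_stokes(flow_problem(bb, "x", pressure_drop = 5))
  expect_false(f$percolating)
  expect_equal(permeability(f), 0)
  expect_equal(f$Q_in, 0)
})

test_that("slab permeability error decreases under grid refinement", {
  errs <- vapply(c(8, 16, 32), function(gap) {
    H <- gap * 3 / 2
    lab <- make_channel_fixture("plane_slab", dims = c(6, H, 10),
                                radius_or_gap = gap, voxel_size_um = 2)
    f <- solve_stokes(flow_problem(lab, "x", pressure_drop = 10))
    k_true <- (gap / H) * (gap * 2)^2 / 12
    abs(permeability(f) / k_true - 1)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("empty box with no-slip walls stays below the slab bound", {
  eb <- make_channel_fixture("empty_box", dims = c(16, 16, 12),
                             voxel_size_um = 2)
  f <- solve_stokes(flow_problem(eb, "x", pressure_drop = 5,
                                 lateral = "noslip"))
  expect_lt(permeability(f), (16 * 2)^2 / 12)
  expect_gt(permeability(f), 0)
})

test_that("aligned channels are permeable only along their axis", {
  arr <- array(1L, c(24, 24, 24))
  for (cz in c(4, 12, 20)) {
    for (cx in c(4, 12, 20)) {
      arr[(cz - 1):(cz + 2), , (cx - 1):(cx + 2)] <- 0L
    }
  }
  lab <- label_volume(arr, 2)
  ky <- permeability(solve_stokes(flow_problem(lab, "y", pressure_drop = 5)))
  kx <- permeability(solve_stokes(flow_problem(lab, "x", pressure_drop = 5)))
  kz <- permeability(solve_stokes(flow_problem(lab, "z", pressure_drop = 5)))
  expect_gt(ky, 0)
  expect_equal(kx, 0)
  expect_equal(kz, 0)
})

test_that("velocity distributions scale linearly and match the parabola", {
  lab <- make_channel_fixture("plane_slab", dims = c(6, 48, 12),
                              radius_or_gap = 32, voxel_size_um = 2)
  f1 <- solve_stokes(flow_problem(lab, "x", pressure_drop = 10))
  f2 <- solve_stokes(flow_problem(lab, "x", pressure_drop = 20))
  v1 <- velocity_distribution(f1)
  v2 <- velocity_distribution(f2)
  expect_equal(attr(v2, "mean_speed") / attr(v1, "mean_speed"), 2,
               tolerance = 1e-6)
  # plane Poiseuille: mean = (2/3) max over the gap
  sp <- mesotissue:::cell_speeds(f1)
  expect_lt(abs(mean(sp) / max(sp) - 2 / 3), 0.03)
})

test_that("streamlines in a straight channel have unit tortuosity", {
  lab <- make_channel_fixture("plane_slab", dims = c(8, 24, 24),
                              radius_or_gap = 12, voxel_size_um = 2)
  f <- solve_stokes(flow_problem(lab, "x", pressure_drop = 10))
  tt <- flow_tortuosity(f, min_length_um = 20, n_streamlines = 40, seed = 2)
  expect_lt(max(abs(tt$tortuosity - 1)), 0.02)
  expect_error(flow_tortuosity(f, min_length_um = 1e5), "min_length")
})

test_that("a jogged duct recovers the centerline tortuosity", {
  arr <- array(1L, c(14, 48, 40))
  arr[4:11, 5:12, 1:20] <- 0L
  arr[4:11, 29:36, 21:40] <- 0L
  arr[4:11, 5:36, 17:24] <- 0L
  lab <- label_volume(arr, 2)
  f <- solve_stokes(flow_problem(lab, "x", pressure_drop = 10))
  tt <- flow_tortuosity(f, min_length_um = 40, n_streamlines = 60, seed = 3)
  # centerline with quarter-circle fillets (radius = half duct width 4)
  legs <- 40 + 24
  fillet <- 2 * (2 - pi / 2) * 4
  tau_ref <- (legs - fillet) / sqrt(40^2 + 24^2)
  expect_lt(abs(attr(tt, "median_tortuosity") - tau_ref) / tau_ref, 0.10)
})

test_that("flow through a Boolean medium has tortuosity between 1 and 3", {
  m <- generate_boolean_medium(synthetic_spec(shape = c(48, 48, 48),
                                              voxel_size_um = 2,
                                              grain_radius_mean = 10,
                                              grain_radius_sd = 2.5,
                                              seed = 17))
  f <- solve_stokes(flow_problem(m, "x"))
  expect_true(f$percolating)
  tt <- flow_tortuosity(f, min_length_um = 40, n_streamlines = 60, seed = 4)
  expect_true(all(tt$tortuosity >= 1 - 1e-6))
  expect_lt(attr(tt, "median_tortuosity"), 3)
})
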