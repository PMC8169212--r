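test_that("Boolean medium hits the target fraction and is reproducible", {
  spec <- synthetic_spec(shape = c(96, 96, 96), voxel_size_um = 2,
                         target_phi = 0.65, seed = 7)
  m1 <- generate_boolean_medium(spec)
  expect_lt(abs(volume_fraction(m1, "tissue") - 0.65), 0.01)
  m2 <- generate_boolean_medium(spec)
  expect_identical(m1$data, m2$data)   # bit-reproducible under the seed
  # different seed changes the realization
  m3 <- generate_boolean_medium(synthetic_spec(shape = c(96, 96, 96),
                                               voxel_size_um = 2, seed = 8))
  expect_false(identical(m1$data, m3$data))
})

test_that("synthetic_spec validates its invariants", {
  expect_error(synthetic_spec(shape = c(8, 96, 96)), ">= 16")
  expect_error(synthetic_spec(target_phi = 1.2), "target_phi")
  expect_error(synthetic_spec(grain_radius_mean = 2, voxel_size_um = 2),
               "2 \\* voxel_size_um")
})

test_that("vessel tree generator returns a consistent ground truth", {
  spec <- synthetic_spec(shape = c(128, 128, 128), voxel_size_um = 2,
                         seed = 1)
  tr <- tree_spec(generations = 2, radius_root = 10, seed = 5)
  vt <- generate_vessel_tree(tr, spec)
  expect_equal(nrow(vt$truth), 7)   # 1 + 2 + 4 branches
  expect_setequal(unique(as.vector(vt$labels$data)), c(0L, 2L))
  # every centerline point lies inside a vessel voxel
  for (i in seq_len(nrow(vt$truth))) {
    pts <- round(vt$truth$path[[i]]) + 1
    expect_true(all(vt$labels$data[pts] == 2L))
  }
  # straight single tube: tortuosity exactly 1
  tr0 <- tree_spec(generations = 0, wiggle_amplitude = 0, seed = 2)
  vt0 <- generate_vessel_tree(tr0, spec)
  expect_equal(nrow(vt0$truth), 1)
  expect_equal(vt0$truth$tortuosity, 1, tolerance = 1e-9)
  # wiggle-free trees have unit tortuosity on every branch
  trs <- tree_spec(generations = 2, wiggle_amplitude = 0, seed = 3)
  vts <- generate_vessel_tree(trs, spec)
  expect_true(all(abs(vts$truth$tortuosity - 1) < 1e-9))
  # unresolvable radius fails loudly
  expect_error(generate_vessel_tree(
    tree_spec(generations = 3, radius_root = 4, radius_decay = 0.5), spec),
    "1.5-voxel")
})

test_that("channel fixtures have the stated geometry", {
  # exact against the center-inclusion rasterization rule ...
  tube <- make_channel_fixture("circular_tube", dims = c(28, 28, 12),
                               radius_or_gap = 10.5, voxel_size_um = 2)
  zz <- (0:27) - 13.5
  disk_count <- sum(outer(zz^2, zz^2, `+`) <= 10.5^2)
  expect_equal(sum(tube$data == 0L), disk_count * 12)
  # ... and within 2% of the continuum cylinder volume
  tube2 <- make_channel_fixture("circular_tube", dims = c(35, 35, 12),
                                radius_or_gap = 14, voxel_size_um = 2)
  expect_lt(abs(sum(tube2$data == 0L) / (pi * 14^2 * 12) - 1), 0.02)
  empty <- make_channel_fixture("empty_box", dims = c(8, 8, 8))
  expect_true(all(empty$data == 0L))
  blocked <- make_channel_fixture("blocked_box", dims = c(8, 8, 10))
  comp <- array(mesotissue:::label_components_cpp(
    as.vector(blocked$data == 0L), dim(blocked$data), 6L),
    dim(blocked$data))
  expect_length(intersect(unique(as.vector(comp[, , 1])),
                          unique(as.vector(comp[, , 10]))), 0)
  expect_error(make_channel_fixture("plane_slab", dims = c(8, 8, 8),
                                    radius_or_gap = 4), ">= 8")
})

test_that("grayscale rendering is deterministic and thresholdable", {
  m <- generate_boolean_medium(synthetic_spec(shape = c(48, 48, 48),
                                              voxel_size_um = 2, seed = 5))
  clean <- render_grayscale(m, blur_sigma = 0, noise_sd = 0, seed = 1)
  rec <- (clean$data >= 0.4) * 1L
  expect_identical(array(rec, dim(rec)),
                   array(as.integer(m$data == 1), dim(m$data)))
  g1 <- render_grayscale(m, blur_sigma = 1, noise_sd = 0.08, seed = 3)
  g2 <- render_grayscale(m, blur_sigma = 1, noise_sd = 0.08, seed = 3)
  expect_identical(g1$data, g2$data)
  # moderate noise: a global threshold still recovers the phase well
  truth <- array(as.integer(m$data == 1), dim(m$data))
  expect_gt(dice((g1$data >= 0.4) * 1L, truth), 0.9)
  expect_error(render_grayscale(m, phase_means = c(pore = 1, tissue = 1,
                                                   vessel = 2)), "distinct")
})

test_that("iid voxel labels decorrelate beyond one voxel", {
  set.seed(42)
  arr <- array(as.integer(runif(48^3) < 0.5), c(48, 48, 48))
  cc <- two_point_autocorrelation(arr, phase = 1, r_max_vox = 10,
                                  voxel_size_um = 1)
  expect_equal(cc$C_mean[cc$r_um == 0], 1)
  npairs <- 48^3
  expect_true(all(abs(cc$C_mean[cc$r_um >= 1]) < 3 / sqrt(npairs)))
})
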