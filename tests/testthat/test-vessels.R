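test_that("a straight tube skeletonizes to a single edge with true metrics", {
  dims <- c(48, 48, 72)
  pts <- cbind(rep(24, 60), rep(24, 60), seq(6, 65, length.out = 60))
  mask <- tube_mask(dims, pts, radius = 4)
  g <- skeletonize(mask, voxel_size_um = 2)
  expect_equal(nrow(g$edges), 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 2)
  expect_equal(sum(g$nodes$kind == "junction"), 0)
  g <- branch_metrics(g, mask)
  expect_equal(g$edges$tortuosity, 1, tolerance = 0.01)
  # diameter: 2 * EDT at the axis, radius 4 voxels at 2 um
  expect_lt(abs(g$edges$diameter_um - 16) / 2, 1)  # within 1 voxel
  # length: capsule medial axis runs between the cap centers
  expect_lt(abs(g$edges$length_um - 118) / 118, 0.05)
})

test_that("a Y-junction yields three branches around one junction node", {
  dims <- c(48, 64, 64)
  trunk <- cbind(rep(24, 40), seq(8, 32, length.out = 40),
                 rep(32, 40))
  arm1 <- cbind(rep(24, 40), seq(32, 56, length.out = 40),
                seq(32, 52, length.out = 40))
  arm2 <- cbind(rep(24, 40), seq(32, 56, length.out = 40),
                seq(32, 12, length.out = 40))
  mask <- tube_mask(dims, trunk, 3.5) | tube_mask(dims, arm1, 3.5) |
    tube_mask(dims, arm2, 3.5)
  g <- suppressMessages(skeletonize(mask, voxel_size_um = 2))
  expect_equal(nrow(g$edges), 3)
  expect_equal(sum(g$nodes$kind == "junction"), 1)
  expect_equal(sum(g$nodes$kind == "endpoint"), 3)
})

test_that("thinning preserves the number of connected components", {
  dims <- c(40, 40, 40)
  m1 <- tube_mask(dims, cbind(c(10, 10), c(8, 32), c(10, 30)), 3)
  m2 <- tube_mask(dims, cbind(c(30, 30), c(8, 32), c(30, 10)), 3)
  mask <- m1 | m2
  g <- skeletonize(mask, voxel_size_um = 1)
  skel_vox <- do.call(rbind, g$edges$path)
  skel <- array(FALSE, dims)
  skel[round(skel_vox) + 1] <- TRUE
  comp_mask <- max(mesotissue:::label_components_cpp(as.vector(mask), dims, 26L))
  comp_skel <- max(mesotissue:::label_components_cpp(as.vector(skel), dims, 26L))
  expect_equal(comp_skel, comp_mask)
})

test_that("quarter-circle tube recovers the analytic tortuosity", {
  th <- seq(0, pi / 2, length.out = 200)
  pts <- cbind(rep(32, 200), 12 + 30 * sin(th), 12 + 30 * (1 - cos(th)))
  mask <- tube_mask(c(64, 64, 64), pts, 4)
  g <- branch_metrics(skeletonize(mask, voxel_size_um = 2), mask)
  expect_equal(nrow(g$edges), 1)
  expect_lt(abs(g$edges$tortuosity - (pi / 2) / sqrt(2)), 0.05)
})

test_that("filter_min_diameter removes thin branches and relabels nodes", {
  dims <- c(40, 48, 48)
  thick <- tube_mask(dims, cbind(c(20, 20), c(8, 40), c(24, 24)), 5)
  thin <- tube_mask(dims, cbind(c(20, 20), c(24, 24), c(24, 44)), 2)
  mask <- thick | thin
  g <- suppressMessages(branch_metrics(
    suppressMessages(skeletonize(mask, voxel_size_um = 2)), mask))
  expect_gte(nrow(g$edges), 2)
  # d_min = 0 is the identity
  expect_equal(nrow(filter_min_diameter(g, 0)$edges), nrow(g$edges))
  filt <- filter_min_diameter(g, d_min_um = 3 * 2)  # 3 voxels
  expect_true(all(filt$edges$diameter_um >= 6))
  expect_true(all(filt$nodes$node %in% c(filt$edges$from, filt$edges$to)))
  # everything below a huge cutoff disappears
  expect_equal(nrow(filter_min_diameter(g, 1e3)$edges), 0)
  # the default cutoff of 3 px at 0.81 um/voxel is 2.43 um
  expect_equal(3 * 0.81, 2.43)
})

test_that("largest_connected_tree picks the longest component deterministically", {
  dims <- c(40, 40, 60)
  long_t <- tube_mask(dims, cbind(c(10, 10), c(20, 20), c(5, 55)), 3)
  short_t <- tube_mask(dims, cbind(c(30, 30), c(20, 20), c(5, 25)), 3)
  mask <- long_t | short_t
  g <- branch_metrics(skeletonize(mask, voxel_size_um = 1), mask)
  expect_equal(nrow(g$edges), 2)
  top <- largest_connected_tree(g)
  expect_equal(nrow(top$edges), 1)
  expect_gt(top$edges$length_um, 40)
  # stable across repeated calls
  expect_identical(largest_connected_tree(g)$nodes, top$nodes)
  # a connected graph is returned unchanged
  g1 <- branch_metrics(skeletonize(long_t, voxel_size_um = 1), long_t)
  expect_equal(nrow(largest_connected_tree(g1)$edges), nrow(g1$edges))
})

test_that("summarize_branches computes linear-interpolation quantiles", {
  g <- structure(list(
    nodes = tibble::tibble(node = 1:2, z = 0, y = 0, x = 0:1,
                           kind = "endpoint", members = list(NULL, NULL)),
    edges = tibble::tibble(edge = 1:5, from = 1L, to = 2L, n_points = 2L,
                           path = replicate(5, cbind(0, 0, 0:1),
                                            simplify = FALSE),
                           length_um = c(1, 2, 3, 4, 5),
                           chord_um = 1, tortuosity = 1,
                           diameter_um = c(1, 2, 3, 4, 5)),
    voxel_size_um = 1, dim = c(2, 2, 2)), class = "skeleton_graph")
  s <- summarize_branches(g, scope = "single_tree")
  lrow <- s[s$metric == "length_um", ]
  expect_equal(lrow$median, 3)
  expect_equal(lrow$q25, 2)
  expect_equal(lrow$q75, 4)
  expect_equal(unique(s$scope), "single_tree")
  # filtering then summarizing equals summarizing the filtered set
  filt <- filter_min_diameter(g, 2.5)
  expect_equal(summarize_branches(filt)$median[1],
               median(g$edges$diameter_um[g$edges$diameter_um >= 2.5]))
  g$edges <- g$edges[0, ]
  expect_error(summarize_branches(g), "no branches")
})

test_that("synthetic tree branches are recovered within stated tolerances", {
  rec <- list()
  for (s in 1:6) {
    spec <- synthetic_spec(shape = c(160, 160, 160), voxel_size_um = 2,
                           seed = s)
    tr <- tree_spec(generations = 2, radius_root = 10, radius_decay = 0.8,
                    segment_length_mean = 80, branch_angle = 40,
                    wiggle_amplitude = 0.15, seed = 100 + s)
    vt <- generate_vessel_tree(tr, spec)
    rec[[s]] <- suppressMessages(assess_tree_recovery(vt))
  }
  rec <- do.call(rbind, rec)
  rec3 <- rec[rec$radius_um / 2 >= 3, ]   # radius >= 3 voxels at 2 um
  ok <- abs(rec3$length_rel_err) <= 0.05 &
    abs(rec3$diameter_err_vox) <= 1 &
    abs(rec3$tortuosity_err) <= 0.05
  expect_gte(mean(ok), 0.95)
})

test_that("coarser voxels degrade diameter accuracy (downsampling caveat)", {
  dims <- c(48, 48, 72)
  pts <- cbind(rep(24, 60), rep(24, 60), seq(6, 65, length.out = 60))
  mask <- tube_mask(dims, pts, radius = 5)
  lab <- label_volume(array(2L * as.integer(mask), dims), 2)
  g1 <- branch_metrics(skeletonize(lab), lab)
  err_full <- abs(median(g1$edges$diameter_um) - 20)
  lab2 <- downsample(lab, 2)
  g2 <- suppressMessages(branch_metrics(skeletonize(lab2), lab2))
  err_down <- abs(median(g2$edges$diameter_um) - 20)
  expect_gt(err_down, err_full)
})

test_that("graph export writes GraphML and a branch table", {
  dims <- c(32, 32, 48)
  mask <- tube_mask(dims, cbind(c(16, 16), c(16, 16), c(5, 43)), 3)
  g <- branch_metrics(skeletonize(mask, voxel_size_um = 2), mask)
  pre <- withr::local_tempfile()
  write_skeleton_graph(g, pre)
  expect_true(file.exists(paste0(pre, ".graphml")))
  tb <- read.csv(paste0(pre, "_branches.csv"))
  expect_equal(nrow(tb), nrow(g$edges))
  expect_true(all(c("length_um", "diameter_um", "tortuosity") %in% names(tb)))
})
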