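test_that("a dumbbell separates into two pores joined by one throat", {
  d <- c(32, 32, 64)
  s1 <- sphere_mask(d, c(15, 15, 16), 10)
  s2 <- sphere_mask(d, c(15, 15, 46), 10)
  co <- arrayInd(seq_len(prod(d)), d) - 1
  neck <- array(sqrt((co[, 1] - 15)^2 + (co[, 2] - 15)^2) <= 3 &
                  co[, 3] >= 16 & co[, 3] <= 46, d)
  lab <- label_volume(array(ifelse(s1 | s2 | neck, 0L, 1L), d), 2)
  pr <- separate_pores(lab, smoothing_sigma = 2)
  expect_equal(pr$n_regions, 2)
  net <- build_pore_network(pr)
  expect_equal(nrow(net$pores), 2)
  expect_equal(nrow(net$throats), 1)
  # inscribed diameters: spheres 2*10 voxels, neck 2*3 voxels (2 um/voxel)
  expect_true(all(abs(net$pores$diameter_um - 40) <= 2))
  expect_lt(abs(net$throats$diameter_um - 12), 2)
  # center-to-center throat length
  expect_equal(net$throats$length_um, 60, tolerance = 2)
  expect_equal(net$pores$coordination, c(1, 1))
})

test_that("a single sphere is one region with zero coordination", {
  d <- c(32, 32, 32)
  pore <- sphere_mask(d, c(15, 15, 15), 9)
  lab <- label_volume(array(ifelse(pore, 0L, 1L), d), 1)
  pr <- separate_pores(lab)
  expect_equal(pr$n_regions, 1)
  net <- build_pore_network(pr)
  expect_equal(net$pores$coordination, 0)
  expect_false(net$pores$touches_boundary)
})

test_that("watershed regions partition the pore phase exactly", {
  m <- generate_boolean_medium(synthetic_spec(shape = c(64, 64, 64),
                                              voxel_size_um = 2, seed = 13))
  pr <- separate_pores(m)
  expect_equal(sum(pr$regions > 0), sum(m$data == 0L))
  net <- build_pore_network(pr)
  expect_equal(sum(net$pores$n_voxels), sum(m$data == 0L))
  expect_true(all(net$throats$pore_a != net$throats$pore_b))
})

test_that("a three-pore chain has coordinations (1, 2, 1)", {
  d <- c(28, 28, 84)
  p1 <- sphere_mask(d, c(13, 13, 14), 9)
  p2 <- sphere_mask(d, c(13, 13, 42), 9)
  p3 <- sphere_mask(d, c(13, 13, 70), 9)
  co <- arrayInd(seq_len(prod(d)), d) - 1
  neck <- array(sqrt((co[, 1] - 13)^2 + (co[, 2] - 13)^2) <= 2.5 &
                  co[, 3] >= 14 & co[, 3] <= 70, d)
  lab <- label_volume(array(ifelse(p1 | p2 | p3 | neck, 0L, 1L), d), 2)
  net <- build_pore_network(separate_pores(lab))
  expect_equal(sort(net$pores$coordination), c(1, 2, 1)[order(c(1, 2, 1))])
  expect_equal(sum(net$pores$coordination == 2), 1)
})

test_that("critical diameter follows bottleneck semantics on chains", {
  # single path: pores 30 and 25 um joined by a 12 um throat -> d* = 12
  pores <- tibble::tibble(pore = 1:2, diameter_um = c(30, 25),
                          touches_boundary = c(FALSE, TRUE))
  throats <- tibble::tibble(pore_a = 1, pore_b = 2, diameter_um = 12)
  net <- pore_network(pores, throats)
  expect_equal(as.numeric(critical_percolation_diameter(net, source = 1)), 12)
  # two parallel paths with bottlenecks 12 and 20 -> d* = 20
  pores2 <- tibble::tibble(pore = 1:4, diameter_um = c(30, 25, 28, 40),
                           touches_boundary = c(FALSE, TRUE, FALSE, TRUE))
  throats2 <- tibble::tibble(pore_a = c(1, 1), pore_b = c(2, 3),
                             diameter_um = c(12, 20))
  throats2 <- rbind(throats2,
                    tibble::tibble(pore_a = 3, pore_b = 4, diameter_um = 35))
  net2 <- pore_network(pores2, throats2)
  expect_equal(as.numeric(critical_percolation_diameter(net2, source = 1)), 20)
  # isolated source returns 0 with a flag
  pores3 <- tibble::tibble(pore = 1:2, diameter_um = c(10, 20),
                           touches_boundary = c(FALSE, TRUE))
  net3 <- pore_network(pores3, throats3 <- tibble::tibble(
    pore_a = integer(0), pore_b = integer(0), diameter_um = numeric(0)))
  d0 <- critical_percolation_diameter(net3, source = 1)
  expect_equal(as.numeric(d0), 0)
  expect_true(attr(d0, "isolated"))
})

test_that("union-find d* equals the exhaustive BFS oracle", {
  for (trial in 1:25) {
    np <- sample(10:120, 1)
    net <- random_network(np, seed = 500 + trial)
    src <- sample(np, 1)
    expect_equal(as.numeric(critical_percolation_diameter(net, source = src)),
                 bfs_critical_diameter(net, src),
                 info = paste("trial", trial))
  }
})

test_that("adding a throat never decreases d*", {
  set.seed(77)
  for (trial in 1:10) {
    np <- sample(10:60, 1)
    net <- random_network(np, seed = 700 + trial)
    src <- sample(np, 1)
    d1 <- as.numeric(critical_percolation_diameter(net, source = src))
    cand <- t(combn(np, 2))
    have <- paste(net$throats$pore_a, net$throats$pore_b)
    cand <- cand[!(paste(cand[, 1], cand[, 2]) %in% have), , drop = FALSE]
    pick <- cand[sample(nrow(cand), 1), ]
    net2 <- pore_network(net$pores,
                         rbind(net$throats,
                               tibble::tibble(pore_a = pick[1],
                                              pore_b = pick[2],
                                              diameter_um = runif(1, 2, 60))))
    d2 <- as.numeric(critical_percolation_diameter(net2, source = src))
    expect_gte(d2, d1)
  }
})

test_that("percolating Boolean media have an essentially connected pore space", {
  m <- generate_boolean_medium(synthetic_spec(shape = c(96, 96, 96),
                                              voxel_size_um = 2, seed = 21))
  mk <- m$data == 0L
  cc <- mesotissue:::label_components_cpp(as.vector(mk), dim(mk), 6L)
  tb <- tabulate(cc)
  # the largest component spans the domain and carries >99% of the pore
  # volume; the remainder is isolated pockets at grain triple-junctions
  expect_gt(max(tb) / sum(tb), 0.99)
})

test_that("random central source draws deterministically under a seed", {
  m <- generate_boolean_medium(synthetic_spec(shape = c(64, 64, 64),
                                              voxel_size_um = 2, seed = 31))
  net <- build_pore_network(separate_pores(m, largest_component = TRUE))
  d1 <- critical_percolation_diameter(net, seed = 5)
  d2 <- critical_percolation_diameter(net, seed = 5)
  expect_identical(d1, d2)
  expect_gt(as.numeric(d1), 0)
})

test_that("summarize_pores reports quantiles and the d*-to-pore ratio", {
  pores <- tibble::tibble(pore = 1:5, diameter_um = c(10, 20, 30, 40, 50),
                          touches_boundary = c(TRUE, rep(FALSE, 4)))
  throats <- tibble::tibble(pore_a = 1:4, pore_b = 2:5,
                            diameter_um = c(5, 10, 15, 20),
                            length_um = c(10, 20, 30, 40))
  net <- pore_network(pores, throats)
  s <- summarize_pores(net, d_star = 15)
  expect_equal(s$median[s$metric == "pore_diameter_um"], 30)
  expect_equal(s$q25[s$metric == "pore_diameter_um"], 20)
  expect_equal(s$median[s$metric == "throat_diameter_um"], 12.5)
  expect_equal(attr(s, "d_star_to_median_pore"), 0.5)
  single <- pore_network(pores[1, ], throats[0, ])
  expect_equal(nrow(summarize_pores(single)), 4)
})
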