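test_that("volume fraction counts voxels", {
  lab <- label_volume(array(1L, c(8, 8, 8)), 1)
  expect_equal(volume_fraction(lab, "tissue"), 1)
  half <- array(0L, c(8, 8, 8)); half[, 1:4, ] <- 1L
  expect_equal(volume_fraction(label_volume(half, 1), "tissue"), 0.5)
})

test_that("surface area estimator is accurate on analytic fixtures", {
  # sphere: 4 pi R^2 within 3% at R = 20 voxels
  d <- c(64, 64, 64)
  sph <- sphere_mask(d, c(31.5, 31.5, 31.5), 20) * 1L
  sv <- specific_surface_area(array(sph, d), phase = 1, voxel_size_um = 1)
  expect_lt(abs(sv / (4 * pi * 20^2 / prod(d)) - 1), 0.03)
  # axis-aligned half-space: triangulated interface is exactly the
  # (n-1)^2 cell-grid plane
  hs <- array(0L, c(32, 32, 32)); hs[, 1:16, ] <- 1L
  svh <- specific_surface_area(hs, phase = 1, voxel_size_um = 1)
  expect_equal(svh, 31^2 / 32^3, tolerance = 1e-9)
  # full-domain phase has no interior interface
  expect_equal(specific_surface_area(array(1L, c(16, 16, 16)), phase = 1,
                                     voxel_size_um = 1), 0)
})

test_that("sphere surface error decreases with radius", {
  sphere_err <- function(R, sigma) {
    n <- 2 * R + 24
    d <- c(n, n, n)
    sph <- sphere_mask(d, rep((n - 1) / 2, 3), R) * 1L
    sv <- specific_surface_area(array(sph, d), phase = 1,
                                smooth_sigma = sigma, voxel_size_um = 1)
    abs(sv / (4 * pi * R^2 / prod(d)) - 1)
  }
  # at heavy smoothing the curvature bias ~ (sigma/R)^2 dominates and the
  # error falls strictly with radius
  errs2 <- vapply(c(10, 20, 40), sphere_err, numeric(1), sigma = 2)
  expect_true(all(diff(errs2) < 0))
  # the default estimator is already at its (small) orientation plateau
  errs <- vapply(c(10, 20, 40), sphere_err, numeric(1), sigma = 0.7)
  expect_true(all(errs < 0.03))
})

test_that("ROI fluctuations: homogeneous volumes and iid closed form", {
  hom <- label_volume(array(1L, c(64, 64, 64)), 2)
  cu <- roi_fluctuations(hom, "tissue", roi_sizes_vox = c(8, 16, 32),
                         z_thickness_um = 32)
  expect_true(all(cu$sd == 0))
  # full-volume ROI: single sample, sd undefined
  cu1 <- roi_fluctuations(hom, "tissue", roi_sizes_vox = 64,
                          z_thickness_um = 128)
  expect_equal(cu1$n_roi, 1)
  expect_true(is.na(cu1$sd))
  # oversized ROI is skipped with a warning
  expect_warning(roi_fluctuations(hom, "tissue", roi_sizes_vox = c(16, 128),
                                  z_thickness_um = 32), "skipped")
  # iid voxels: sd/mean = sqrt((1-phi)/(phi N)) within 10%
  set.seed(12)
  phi <- 0.6
  iid <- label_volume(array(as.integer(runif(64^3) < phi), c(64, 64, 64)), 1)
  cu2 <- roi_fluctuations(iid, "tissue", roi_sizes_vox = c(8, 16),
                          z_thickness_um = 8)
  for (i in 1:2) {
    N <- cu2$size_vox[i]^2 * 8
    expect_lt(abs(cu2$rel_err[i] / sqrt((1 - phi) / (phi * N)) - 1), 0.10)
  }
})

test_that("scaling exponent fit recovers constructed and iid slopes", {
  # synthetic curve with exact sd/mean = c V^(-1/2) -> slope -0.5 exactly
  v <- c(1e4, 1e5, 1e6, 1e7)
  curve <- tibble::tibble(size_vox = c(10, 21, 46, 100),
                          size_um = c(10, 21, 46, 100),
                          size_eff_um = v^(1 / 3), v_roi_um3 = v,
                          n_roi = 100, mean = 0.6, sd = 0.6 * 2 * v^(-0.5),
                          rel_err = 2 * v^(-0.5))
  class(curve) <- c("roi_scale_curve", class(curve))
  attr(curve, "samples") <- lapply(seq_along(v), function(i) rnorm(50))
  names(attr(curve, "samples")) <- as.character(curve$size_vox)
  fit <- suppressWarnings(fit_scaling_exponent(curve, n_boot = 10))
  expect_equal(fit$slope, -0.5, tolerance = 1e-9)
  expect_equal(fit$halving_volume_ratio, 4, tolerance = 1e-9)
  expect_equal(tidy(fit)$estimate, fit$slope)
  expect_equal(suppressWarnings(glance(fit))$n_sizes, 4)
  # iid voxel medium: slope -0.5 within 0.05 using all sizes
  set.seed(14)
  iid <- label_volume(array(as.integer(runif(96^3) < 0.6), c(96, 96, 96)), 1)
  cu <- roi_fluctuations(iid, "tissue", roi_sizes_vox = c(8, 12, 16, 24, 32),
                         z_thickness_um = 16)
  f2 <- fit_scaling_exponent(cu, n_boot = 20)
  expect_lt(abs(f2$slope + 0.5), 0.05)
  expect_error(fit_scaling_exponent(cu, min_size_um = 1e6), "at least 3")
})

test_that("sd/mean is non-increasing in ROI volume on nested families", {
  m <- generate_boolean_medium(synthetic_spec(shape = c(96, 96, 96),
                                              voxel_size_um = 2, seed = 19))
  cu <- roi_fluctuations(m, "tissue", roi_sizes_vox = c(8, 16, 32),
                         z_thickness_um = 64)
  expect_true(all(diff(cu$rel_err) < 0))
})

test_that("FFT autocorrelation matches a pair-sampling oracle", {
  m <- generate_boolean_medium(synthetic_spec(shape = c(48, 48, 48),
                                              voxel_size_um = 2,
                                              grain_radius_mean = 8,
                                              grain_radius_sd = 2, seed = 23))
  cc <- two_point_autocorrelation(m, "tissue", r_max_vox = 12)
  expect_equal(cc$C_mean[cc$r_um == 0], 1)
  mk <- m$data == 1L
  phi <- mean(mk)
  # compare S2 at axis lags against Monte-Carlo pair counting
  lags <- rbind(c(2, 0, 0), c(0, 4, 0), c(0, 0, 6), c(3, 3, 0))
  s2_mc <- pair_sampling_s2(mk, lags, n_pairs = 200000, seed = 99)
  c_mc <- (s2_mc - phi^2) / (phi - phi^2)
  for (i in seq_len(nrow(lags))) {
    r <- sqrt(sum(lags[i, ]^2)) * 2
    row <- which.min(abs(cc$r_um - r))
    mc_se <- 3 * sqrt(s2_mc[i] * (1 - s2_mc[i]) / 200000) / (phi - phi^2)
    # radial bin mixes directions; allow the bin spread on top of MC error
    tol <- mc_se + cc$C_sd[row] + 0.02
    expect_lt(abs(cc$C_mean[row] - c_mc[i]), tol)
  }
})

test_that("periodic and padded estimators agree at short lags", {
  m <- generate_boolean_medium(synthetic_spec(shape = c(48, 48, 48),
                                              voxel_size_um = 2,
                                              grain_radius_mean = 8,
                                              grain_radius_sd = 2, seed = 29))
  c1 <- two_point_autocorrelation(m, "tissue", r_max_vox = 6,
                                  estimator = "padded")
  c2 <- two_point_autocorrelation(m, "tissue", r_max_vox = 6,
                                  estimator = "periodic")
  expect_lt(max(abs(c1$C_mean - c2$C_mean)), 0.05)
  expect_error(two_point_autocorrelation(array(1L, c(16, 16, 16)), phase = 1,
                                         voxel_size_um = 1), "undefined")
})

test_that("correlation length inverts analytic and ordered cases", {
  # exponential curve exp(-r/50): 1% crossing at 50 ln(100) = 230.3 um
  r <- seq(0, 400, by = 2)
  curve <- tibble::tibble(r_um = r, C_mean = exp(-r / 50), C_sd = 0,
                          n_lags = 1L)
  class(curve) <- c("correlation_curve", class(curve))
  expect_equal(correlation_length(curve), 50 * log(100), tolerance = 0.5)
  short <- curve[curve$r_um <= 100, ]
  class(short) <- c("correlation_curve", class(short))
  expect_error(correlation_length(short), "never falls")
  # iid medium decorrelates within ~1 voxel
  set.seed(31)
  iid <- array(as.integer(runif(32^3) < 0.5), c(32, 32, 32))
  ci <- two_point_autocorrelation(iid, phase = 1, r_max_vox = 8,
                                  voxel_size_um = 1)
  expect_lte(correlation_length(ci), 2)
  # correlation length grows with grain radius (two-seed mean curves
  # smooth out the single-realization plateau at large lags)
  lams <- vapply(c(6, 9, 12), function(gr) {
    cs <- lapply(1:2, function(s) two_point_autocorrelation(
      generate_boolean_medium(synthetic_spec(
        shape = c(96, 96, 96), voxel_size_um = 2, grain_radius_mean = gr,
        grain_radius_sd = gr / 4, seed = 36 + s)), "tissue",
      r_max_vox = 40))
    mc <- cs[[1]]
    mc$C_mean <- (cs[[1]]$C_mean + cs[[2]]$C_mean) / 2
    correlation_length(mc)
  }, numeric(1))
  expect_true(all(diff(lams) > 0))
})
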