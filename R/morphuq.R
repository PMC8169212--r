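#' Phase volume fraction
#'
#' @param labels a [label_volume()] or array.
#' @param phase phase value or legend name.
#' @return Fraction of voxels in the phase.
#' @export
volume_fraction <- function(labels, phase = "tissue") {
  mean(phase_mask(labels, phase))
}

#' Specific surface area of a phase interface
#'
#' `S_V` is the triangulated area of the 0.5 iso-surface of the phase
#' indicator divided by the total domain volume (um^-1). The indicator
#' is lightly Gaussian-smoothed before triangulation (default sigma of
#' 0.7 voxels), which moves iso-surface vertices off the lattice midpoints
#' and removes most voxelization bias; domain faces are never counted
#' as interface.
#'
#' @param labels a [label_volume()] or array.
#' @param phase phase value or legend name.
#' @param smooth_sigma pre-smoothing sd in voxels (0 disables).
#' @param voxel_size_um voxel size for a bare array.
#' @return Specific surface area in um^-1.
#' @export
specific_surface_area <- function(labels, phase = "tissue",
                                  smooth_sigma = 0.7, voxel_size_um = NULL) {
  mk <- phase_mask(labels, phase)
  h <- if (is_label_volume(labels)) labels$voxel_size_um else
    voxel_size_um %||% stop("`voxel_size_um` required for a bare array")
  if (!any(mk)) stop("phase is empty")
  d <- dim(mk)
  ind <- array(as.numeric(mk), dim = d)
  if (smooth_sigma > 0) ind <- gaussian_blur3(ind, smooth_sigma)
  area_vox2 <- iso_area_cpp(as.vector(ind), d, 0.5)
  area_vox2 * h^2 / (prod(d) * h^3)
}

#' ROI-resampled fluctuation curve of a morphological metric
#'
#' The volume is tiled into non-overlapping ROIs with square `x`-`y`
#' extent and a fixed `z` thickness; per ROI the metric (volume
#' fraction, or specific surface area) is computed, and for each ROI
#' size the mean, standard deviation and relative error sd/mean are
#' recorded. When a size yields more than `max_rois` tiles, every n-th
#' tile in (z, y, x) tile order is kept (systematic sampling).
#'
#' @param labels a [label_volume()].
#' @param phase phase value or legend name.
#' @param roi_sizes_vox integer vector of square x-y ROI edge lengths in
#'   voxels.
#' @param z_thickness_um fixed ROI thickness along z in micrometres
#'   (rounded to voxels, capped at the volume depth; default 243.75).
#' @param metric `"phi"` (volume fraction) or `"sv"` (specific surface
#'   area, slower).
#' @param max_rois systematic-sampling cap per size.
#' @param n_offsets number of systematic tiling offsets per ROI size.
#'   With 1 the tiling is anchored at the volume origin; larger values
#'   add shifted non-overlapping tilings (offset by `s/n_offsets` steps
#'   in y and x), which stabilizes the sd estimate when a size admits
#'   only a few tiles. Samples from all tilings are pooled per size.
#' @return A `roi_scale_curve` tibble: size_vox, size_um (x-y edge),
#'   size_eff_um (cube root of the ROI volume), v_roi_um3, n_roi, mean,
#'   sd, rel_err; per-ROI samples are kept in attribute `samples`.
#' @export
roi_fluctuations <- function(labels, phase = "tissue",
                             roi_sizes_vox = c(16, 24, 32, 48, 64, 96),
                             z_thickness_um = 243.75, metric = c("phi", "sv"),
                             max_rois = 1000, n_offsets = 1) {
  stopifnot(is_label_volume(labels))
  metric <- match.arg(metric)
  h <- labels$voxel_size_um
  d <- dim(labels$data)
  zt <- min(max(1L, as.integer(round(z_thickness_um / h))), d[1])
  mk <- phase_mask(labels, phase)
  S <- if (metric == "phi") integral_image3(array(as.numeric(mk), dim = d))
  rows <- list()
  samples <- list()
  for (s in roi_sizes_vox) {
    if (s > d[2] || s > d[3]) {
      warning(sprintf("ROI size %d exceeds volume extent; skipped", s))
      next
    }
    tiles <- NULL
    offs <- floor((seq_len(n_offsets) - 1) * s / n_offsets)
    for (offy in offs) {
      for (offx in offs) {
        ntz <- d[1] %/% zt
        nty <- (d[2] - offy) %/% s
        ntx <- (d[3] - offx) %/% s
        if (nty < 1 || ntx < 1) next
        tk <- expand.grid(tz = seq_len(ntz) - 1L, ty = seq_len(nty) - 1L,
                          tx = seq_len(ntx) - 1L)
        tk$oy <- offy + tk$ty * s
        tk$ox <- offx + tk$tx * s
        # (z, y, x) tile order for the systematic n-th pick
        tk <- tk[order(tk$tz, tk$ty, tk$tx), ]
        if (nrow(tk) > max_rois) {
          step <- nrow(tk) / max_rois
          tk <- tk[unique(ceiling(seq_len(max_rois) * step)), ]
        }
        tiles <- rbind(tiles, tk)
      }
    }
    vals <- numeric(nrow(tiles))
    for (r in seq_len(nrow(tiles))) {
      o <- c(tiles$tz[r] * zt, tiles$oy[r], tiles$ox[r])
      e <- c(zt, s, s)
      if (metric == "phi") {
        vals[r] <- box_sum(S, o, e) / prod(e)
      } else {
        sub <- mk[o[1] + seq_len(e[1]), o[2] + seq_len(e[2]),
                  o[3] + seq_len(e[3]), drop = FALSE]
        vals[r] <- if (any(sub)) {
          specific_surface_area(array(as.integer(sub), dim = e), phase = 1,
                                voxel_size_um = h)
        } else 0
      }
    }
    mu <- mean(vals)
    sdv <- if (length(vals) > 1) stats::sd(vals) else NA_real_
    v_roi <- prod(c(zt, s, s)) * h^3
    rows[[length(rows) + 1]] <- tibble::tibble(
      size_vox = s, size_um = s * h, size_eff_um = v_roi^(1 / 3),
      v_roi_um3 = v_roi, n_roi = length(vals), mean = mu, sd = sdv,
      rel_err = sdv / mu)
    samples[[as.character(s)]] <- vals
  }
  out <- dplyr::bind_rows(rows)
  class(out) <- c("roi_scale_curve", class(out))
  attr(out, "samples") <- samples
  attr(out, "metric") <- metric
  attr(out, "voxel_size_um") <- h
  out
}

#' Fit the scaling exponent of relative fluctuations versus ROI volume
#'
#' Ordinary least squares of `log(sd/mean)` on `log(V_ROI)` restricted
#' to ROI sizes at least `min_size_um` (in x-y edge length; pass about
#' twice the correlation length so the asymptotic regime is fitted).
#' The confidence interval comes from a bootstrap over the per-size ROI
#' samples.
#'
#' @param curve a `roi_scale_curve` from [roi_fluctuations()].
#' @param min_size_um smallest x-y ROI edge admitted to the fit.
#' @param n_boot bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return A `scaling_fit` object with `slope`, `ci` and the fitted
#'   points; see [tidy.scaling_fit()].
#' @export
fit_scaling_exponent <- function(curve, min_size_um = 0, n_boot = 200,
                                 seed = 1) {
  stopifnot(inherits(curve, "roi_scale_curve"))
  use <- curve$size_um >= min_size_um & is.finite(curve$rel_err) &
    curve$rel_err > 0
  if (sum(use) < 3) {
    stop("need at least 3 ROI sizes above min_size_um with defined sd/mean")
  }
  pts <- curve[use, ]
  fit <- stats::lm(log(rel_err) ~ log(v_roi_um3), data = pts)
  slope <- unname(stats::coef(fit)[2])
  samples <- attr(curve, "samples")
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    re <- vapply(as.character(pts$size_vox), function(sv) {
      x <- samples[[sv]]
      x <- x[sample.int(length(x), replace = TRUE)]
      stats::sd(x) / mean(x)
    }, numeric(1))
    ok <- is.finite(re) & re > 0
    if (sum(ok) < 2) return(NA_real_)
    unname(stats::coef(stats::lm(log(re[ok]) ~ log(pts$v_roi_um3[ok])))[2])
  }, numeric(1)))
  ci <- stats::quantile(boots, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  structure(list(slope = slope, ci = ci, points = pts, fit = fit,
                 n_boot = n_boot,
                 halving_volume_ratio = 2^(1 / abs(slope))),
            class = "scaling_fit")
}

#' @export
print.scaling_fit <- function(x, ...) {
  cat(sprintf("<scaling_fit> slope %.3f (95%% CI %.3f..%.3f) over %d sizes\n",
              x$slope, x$ci[1], x$ci[2], nrow(x$points)))
  cat(sprintf("  ROI-volume ratio halving sd/mean: %.2f\n",
              x$halving_volume_ratio))
  invisible(x)
}

#' @rdname fit_scaling_exponent
#' @param x a `scaling_fit`.
#' @param ... unused.
#' @export
tidy.scaling_fit <- function(x, ...) {
  tibble::tibble(term = "log(V_ROI)", estimate = x$slope,
                 conf.low = x$ci[1], conf.high = x$ci[2])
}

#' @rdname fit_scaling_exponent
#' @export
glance.scaling_fit <- function(x, ...) {
  tibble::tibble(slope = x$slope, conf.low = x$ci[1], conf.high = x$ci[2],
                 halving_volume_ratio = x$halving_volume_ratio,
                 n_sizes = nrow(x$points),
                 r.squared = summary(x$fit)$r.squared)
}

#' Radial two-point autocorrelation of a phase indicator
#'
#' Computes the normalized autocovariance
#' `C(r) = (S2(r) - phi^2) / (phi - phi^2)` where `S2` is the two-point
#' probability of the phase, estimated by FFT autocorrelation with
#' radial binning of one voxel. The default `"padded"` estimator
#' zero-pads and divides by the exact overlap count (unbiased for a
#' non-periodic sample); `"periodic"` treats the volume as a torus.
#'
#' @param labels a [label_volume()] or array.
#' @param phase phase value or legend name.
#' @param r_max_vox largest lag in voxels (default: a third of the
#'   smallest extent).
#' @param estimator boundary handling, `"padded"` or `"periodic"`.
#' @param voxel_size_um voxel size for a bare array.
#' @return A `correlation_curve` tibble: r_um, C_mean, C_sd (spread over
#'   equal-radius lags), n_lags; attribute `phi`.
#' @export
two_point_autocorrelation <- function(labels, phase = "tissue",
                                      r_max_vox = NULL,
                                      estimator = c("padded", "periodic"),
                                      voxel_size_um = NULL) {
  estimator <- match.arg(estimator)
  mk <- phase_mask(labels, phase)
  h <- if (is_label_volume(labels)) labels$voxel_size_um else
    voxel_size_um %||% stop("`voxel_size_um` required for a bare array")
  d <- dim(mk)
  phi <- mean(mk)
  if (phi == 0 || phi == 1) {
    stop("autocorrelation normalization undefined for phi = ", phi)
  }
  if (is.null(r_max_vox)) r_max_vox <- floor(min(d) / 3)
  r_max_vox <- min(r_max_vox, min(d) - 1)
  ind <- array(as.numeric(mk), dim = d)
  if (estimator == "padded") {
    pd <- vapply(d + r_max_vox, next_fast_len, integer(1))
    big <- array(0, dim = pd)
    big[seq_len(d[1]), seq_len(d[2]), seq_len(d[3])] <- ind
    F <- fft(big)
    raw <- Re(fft(F * Conj(F), inverse = TRUE)) / prod(pd)
    # exact overlap counts for lags up to r_max (no circular pollution)
    cnt <- outer(outer(pmax(d[1] - lag_abs(pd[1]), 0),
                       pmax(d[2] - lag_abs(pd[2]), 0)),
                 pmax(d[3] - lag_abs(pd[3]), 0))
    dim(cnt) <- pd
    S2 <- raw / pmax(cnt, 1)
  } else {
    F <- fft(ind)
    S2 <- Re(fft(F * Conj(F), inverse = TRUE)) / (prod(d) * prod(d))
    pd <- d
  }
  # gather lags within r_max
  m <- r_max_vox
  sel_axis <- function(n) c(1:(m + 1), if (m >= 1) (n - m + 1):n)
  lag_vals <- function(n) c(0:m, if (m >= 1) -(m:1))
  iz <- sel_axis(pd[1]); iy <- sel_axis(pd[2]); ix <- sel_axis(pd[3])
  sub <- S2[iz, iy, ix]
  lz <- lag_vals(pd[1]); ly <- lag_vals(pd[2]); lx <- lag_vals(pd[3])
  rr <- sqrt(outer(outer(lz^2, ly^2, `+`), lx^2, `+`))
  dim(rr) <- dim(sub)
  okr <- rr <= m + 1e-9
  bins <- floor(rr[okr] + 0.5)      # 1-voxel radial bins centered on r
  Cn <- (sub[okr] - phi^2) / (phi - phi^2)
  agg_m <- tapply(Cn, bins, mean)
  agg_s <- tapply(Cn, bins, stats::sd)
  agg_n <- tapply(Cn, bins, length)
  r_vox <- as.numeric(names(agg_m))
  out <- tibble::tibble(r_um = r_vox * h, C_mean = as.numeric(agg_m),
                        C_sd = as.numeric(agg_s),
                        n_lags = as.integer(agg_n))
  out <- out[order(out$r_um), ]
  class(out) <- c("correlation_curve", class(out))
  attr(out, "phi") <- phi
  attr(out, "voxel_size_um") <- h
  out
}

lag_abs <- function(n) {
  k <- 0:(n - 1)
  pmin(k, n - k)
}

#' Correlation length from an autocorrelation curve
#'
#' The smallest distance at which the mean normalized autocorrelation
#' falls below `threshold` (default 1%), with linear interpolation
#' between radial bins.
#'
#' @param curve a `correlation_curve`.
#' @param threshold decay threshold on the normalized correlation.
#' @return Correlation length in micrometres.
#' @export
correlation_length <- function(curve, threshold = 0.01) {
  stopifnot(inherits(curve, "correlation_curve"))
  r <- curve$r_um
  C <- curve$C_mean
  below <- which(C < threshold)
  if (!length(below)) {
    stop(sprintf("correlation never falls below %.3g within r_max = %.4g um",
                 threshold, max(r)))
  }
  k <- below[1]
  if (k == 1) return(r[1])
  # linear interpolation between the bracketing bins
  r[k - 1] + (threshold - C[k - 1]) * (r[k] - r[k - 1]) / (C[k] - C[k - 1])
}
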