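#' Virtual 2D stereology design
#'
#' Defaults mirror a classical CT-based protocol: every 100th slice, an
#' 11 x 11 point grid in a 1800 x 1800 px field of view for volume
#' density, and a 10 x 10 grid of crosses with 12 um horizontal test
#' lines in a 543 x 543 px field of view for surface density.
#'
#' @param every_k slice sampling interval.
#' @param fov_vv_px field-of-view edge for point counting, pixels.
#' @param fov_sv_px field-of-view edge for intercept counting, pixels.
#' @param grid_points point-grid edge count (`grid_points^2` points).
#' @param grid_crosses cross-grid edge count.
#' @param line_length_um test-line length per cross, micrometres.
#' @return A `stereology_design` list.
#' @export
stereology_design <- function(every_k = 100, fov_vv_px = 1800,
                              fov_sv_px = 543, grid_points = 11,
                              grid_crosses = 10, line_length_um = 12) {
  stopifnot(every_k >= 1, grid_points >= 2, grid_crosses >= 1,
            line_length_um > 0)
  structure(list(every_k = as.integer(every_k),
                 fov_vv_px = as.integer(fov_vv_px),
                 fov_sv_px = as.integer(fov_sv_px),
                 grid_points = as.integer(grid_points),
                 grid_crosses = as.integer(grid_crosses),
                 line_length_um = line_length_um),
            class = "stereology_design")
}

#' Systematically sample z-slices from a volume
#'
#' Slices at 0-based indices `0, k, 2k, ...`; a 2120-slice stack at
#' `k = 100` yields 22 images.
#'
#' @param vol a volume object or 3D array.
#' @param every_k sampling interval (>= 1).
#' @return A list with `indices` (0-based) and `slices` (list of
#'   `(y, x)` matrices).
#' @export
sample_slices <- function(vol, every_k = 100) {
  stopifnot(every_k >= 1)
  a <- vol_data(vol)
  d <- dim(a)
  idx0 <- seq(0, d[1] - 1, by = every_k)
  list(indices = as.integer(idx0),
       slices = lapply(idx0 + 1, function(k) array(a[k, , ], d[2:3])))
}

# systematic FOV placement: centered, with an optional (dy, dx) offset
fov_origin <- function(img_dim, fov, offset = c(0, 0)) {
  if (any(fov > img_dim)) {
    stop(sprintf("FOV %d px exceeds image extent %s", fov,
                 paste(img_dim, collapse = "x")))
  }
  o <- floor((img_dim - fov) / 2) + offset
  o <- pmax(0, pmin(o, img_dim - fov))
  o
}

#' Point-count volume density on a 2D binary image
#'
#' An `n x n` dot grid is superimposed on the field of view at uniform
#' spacing (dot `i` at fractional position `(i - 0.5)/n` of the FOV
#' edge); `V_V = P_p / P_n` with `P_p` the dots landing on the phase
#' and `P_n = n^2`.
#'
#' @param image 2D binary matrix (1 = phase of interest).
#' @param grid_n grid edge count.
#' @param fov_px FOV edge in pixels (default: full image, clipped to
#'   square).
#' @param offset integer `(dy, dx)` FOV displacement from centered
#'   placement.
#' @return A one-row tibble: `p_p`, `p_n`, `v_v`.
#' @export
point_count_vv <- function(image, grid_n = 11, fov_px = NULL,
                           offset = c(0, 0)) {
  d <- dim(image)
  if (is.null(fov_px)) fov_px <- min(d)
  o <- fov_origin(d, fov_px, offset)
  pos <- floor((seq_len(grid_n) - 0.5) / grid_n * fov_px)
  ys <- o[1] + pos + 1
  xs <- o[2] + pos + 1
  hits <- image[ys, xs, drop = FALSE]
  p_p <- sum(hits > 0)
  tibble::tibble(p_p = p_p, p_n = grid_n^2, v_v = p_p / grid_n^2)
}

#' Line-intercept surface density on a 2D binary image
#'
#' Horizontal test lines of the given physical length are centered on
#' the crosses of an `n x n` grid in the field of view; boundary
#' crossings are counted as transitions of the binary profile along
#' each line at pixel resolution. `I_L` is the total intersection count
#' per total test-line length, and `S_V = 2 I_L` for isotropic
#' structures.
#'
#' @param image 2D binary matrix.
#' @param voxel_size_um pixel size, micrometres.
#' @param grid_n cross-grid edge count.
#' @param line_length_um test-line length, micrometres.
#' @param fov_px FOV edge in pixels (default: full image, clipped).
#' @param offset `(dy, dx)` FOV displacement.
#' @return A one-row tibble: `intersections`, `total_line_um`, `i_l`,
#'   `s_v` (um^-1).
#' @export
intercept_count_sv <- function(image, voxel_size_um, grid_n = 10,
                               line_length_um = 12, fov_px = NULL,
                               offset = c(0, 0)) {
  d <- dim(image)
  if (is.null(fov_px)) fov_px <- min(d)
  o <- fov_origin(d, fov_px, offset)
  len_px <- max(2L, as.integer(round(line_length_um / voxel_size_um)))
  pos <- floor((seq_len(grid_n) - 0.5) / grid_n * fov_px)
  total_cross <- 0L
  total_len_px <- 0L
  for (gy in pos) {
    for (gx in pos) {
      y <- o[1] + gy + 1
      x0 <- o[2] + gx + 1 - len_px %/% 2
      x1 <- x0 + len_px - 1
      x0 <- max(1, x0)
      x1 <- min(d[2], x1)
      if (x1 <= x0) next
      prof <- image[y, x0:x1] > 0
      total_cross <- total_cross + sum(abs(diff(prof)))
      total_len_px <- total_len_px + (x1 - x0)
    }
  }
  if (total_len_px == 0) stop("zero total test-line length")
  i_l <- total_cross / (total_len_px * voxel_size_um)
  tibble::tibble(intersections = total_cross,
                 total_line_um = total_len_px * voxel_size_um,
                 i_l = i_l, s_v = 2 * i_l)
}

#' Full virtual-stereology pass over a label volume
#'
#' Samples every k-th slice, applies point counting and line-intercept
#' counting per slice and aggregates.
#'
#' @param labels a [label_volume()].
#' @param phase phase of interest.
#' @param design a [stereology_design()].
#' @return A `stereology_result`: per-image tibble plus a `summary`
#'   attribute with mean and sd of `v_v` and `s_v`.
#' @export
stereology_volume <- function(labels, phase = "tissue",
                              design = stereology_design()) {
  stopifnot(is_label_volume(labels), inherits(design, "stereology_design"))
  h <- labels$voxel_size_um
  mk <- phase_mask(labels, phase)
  sl <- sample_slices(mk * 1L, design$every_k)
  d2 <- dim(sl$slices[[1]])
  fov_vv <- min(design$fov_vv_px, d2)
  fov_sv <- min(design$fov_sv_px, d2)
  rows <- purrr::map2_dfr(sl$slices, sl$indices, function(img, idx) {
    vv <- point_count_vv(img, grid_n = design$grid_points, fov_px = fov_vv)
    sv <- intercept_count_sv(img, voxel_size_um = h,
                             grid_n = design$grid_crosses,
                             line_length_um = design$line_length_um,
                             fov_px = fov_sv)
    dplyr::bind_cols(tibble::tibble(slice = idx), vv, sv)
  })
  out <- rows
  class(out) <- c("stereology_result", class(out))
  attr(out, "summary") <- tibble::tibble(
    v_v_mean = mean(rows$v_v), v_v_sd = stats::sd(rows$v_v),
    s_v_mean = mean(rows$s_v), s_v_sd = stats::sd(rows$s_v),
    n_images = nrow(rows))
  out
}

#' Cross-validate 2D stereology against direct 3D morphometrics
#'
#' @param stereo a `stereology_result`.
#' @param phi_3d direct 3D volume fraction of the same phase.
#' @param sv_3d direct 3D specific surface area (um^-1).
#' @return A tibble comparing the estimates with relative differences.
#' @export
compare_2d_3d <- function(stereo, phi_3d, sv_3d) {
  stopifnot(inherits(stereo, "stereology_result"))
  s <- attr(stereo, "summary")
  tibble::tibble(
    metric = c("volume_fraction", "specific_surface_area_um1"),
    estimate_2d = c(s$v_v_mean, s$s_v_mean),
    sd_2d = c(s$v_v_sd, s$s_v_sd),
    estimate_3d = c(phi_3d, sv_3d),
    rel_diff = c((s$v_v_mean - phi_3d) / phi_3d,
                 (s$s_v_mean - sv_3d) / sv_3d))
}
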