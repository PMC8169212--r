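#' Specification of a synthetic two-phase Boolean medium
#'
#' The tissue phase is modelled as a Boolean medium: a union of spheres
#' with Poisson-distributed centers and lognormal radii, thresholded so
#' that the realized tissue volume fraction hits `target_phi` within
#' +/- 0.01. The construction reproduces the two statistics the analysis
#' relies on -- a prescribed solid fraction and a finite correlation
#' length set by the grain size -- without attempting to mimic villous
#' branching morphology.
#'
#' @param shape integer extents `(z, y, x)` in voxels, each >= 16.
#' @param voxel_size_um voxel edge, micrometres.
#' @param target_phi tissue volume fraction in (0, 1).
#' @param grain_radius_mean,grain_radius_sd lognormal grain radius moments
#'   (micrometres); the mean must be at least `2 * voxel_size_um` so grains
#'   are resolvable.
#' @param seed integer seed; all generators are bit-reproducible under it.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(shape = c(192, 192, 192), voxel_size_um = 2,
                           target_phi = 0.65, grain_radius_mean = 16,
                           grain_radius_sd = 4, seed = 1) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3)
  if (any(shape < 16)) stop("every `shape` component must be >= 16")
  if (!(target_phi > 0 && target_phi < 1)) stop("`target_phi` must be in (0,1)")
  if (voxel_size_um <= 0) stop("`voxel_size_um` must be positive")
  if (grain_radius_mean < 2 * voxel_size_um) {
    stop("`grain_radius_mean` must be >= 2 * voxel_size_um (got ",
         grain_radius_mean, " um at ", voxel_size_um, " um/voxel)")
  }
  if (grain_radius_sd < 0) stop("`grain_radius_sd` must be >= 0")
  structure(list(shape = shape, voxel_size_um = voxel_size_um,
                 target_phi = target_phi,
                 grain_radius_mean = grain_radius_mean,
                 grain_radius_sd = grain_radius_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

# lognormal parameters from mean/sd on the natural scale
lognormal_params <- function(m, s) {
  if (s <= 0) return(list(meanlog = log(m), sdlog = 0))
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

#' Generate a Boolean two-phase medium
#'
#' Spheres are drawn from a Poisson process in a domain padded by the
#' largest radius (so the medium is statistically stationary up to the
#' boundary) and rasterized one by one under the center-inclusion rule;
#' the number of spheres kept is the smallest prefix whose realized
#' tissue fraction is closest to `target_phi`. Fails if the target cannot
#' be approached within +/- 0.01.
#'
#' @param spec a [synthetic_spec()].
#' @return A [label_volume()] with phases pore (0) and tissue (1).
#' @export
generate_boolean_medium <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  h <- spec$voxel_size_um
  d <- spec$shape
  lp <- lognormal_params(spec$grain_radius_mean / h, spec$grain_radius_sd / h)
  mean_vol <- if (lp$sdlog == 0) {
    4 / 3 * pi * exp(3 * lp$meanlog)
  } else {
    4 / 3 * pi * exp(3 * lp$meanlog + 4.5 * lp$sdlog^2)
  }
  # Boolean model: phi = 1 - exp(-lambda * E[V]). For a Poisson process the
  # coverage probability of a voxel center is exact with the continuous
  # sphere volume, so the analytic intensity is unbiased; the natural
  # Poisson draw is accepted whenever it lands within the +/- 0.01
  # tolerance (keeping the ensemble's own fluctuations intact), and only
  # an out-of-tolerance draw is bisected back to the tolerance edge.
  lambda <- -log(1 - spec$target_phi) / mean_vol
  with_seed(spec$seed, {
    rmax_guess <- exp(lp$meanlog + 4 * lp$sdlog)
    pad <- ceiling(rmax_guess)
    ext <- d + 2 * pad
    n_nat <- stats::rpois(1, lambda * prod(ext))
    n_pool <- max(2 * n_nat, n_nat + 50)           # reserve for bisection
    centers <- cbind(stats::runif(n_pool, -pad, d[1] - 1 + pad),
                     stats::runif(n_pool, -pad, d[2] - 1 + pad),
                     stats::runif(n_pool, -pad, d[3] - 1 + pad))
    radii <- stats::rlnorm(n_pool, lp$meanlog, lp$sdlog)
  })
  res <- stamp_balls_cpp(d, centers, radii)
  frac <- res$cumulative_covered / prod(d)
  tol <- 0.01
  if (abs(frac[n_nat] - spec$target_phi) <= tol) {
    k <- n_nat
  } else {
    # smallest adjustment that brings the fraction inside the tolerance
    inside <- which(abs(frac - spec$target_phi) <= tol)
    if (!length(inside)) {
      stop(sprintf(paste0("target_phi = %.3f unreachable with these grains; ",
                          "achievable range with this pool is [0, %.3f]"),
                   spec$target_phi, max(frac)))
    }
    k <- inside[which.min(abs(inside - n_nat))]
  }
  if (k < length(radii)) {
    res <- stamp_balls_cpp(d, centers[seq_len(k), , drop = FALSE],
                           radii[seq_len(k)])
  }
  lab <- array(as.integer(res$mask), dim = d)
  out <- label_volume(lab, h)
  attr(out, "realized_phi") <- frac[k]
  attr(out, "n_grains") <- k
  out
}

#' Specification of a synthetic branching vessel tree
#'
#' A recursive bifurcating tube tree: each branch is a wiggly polyline of
#' given mean segment length; children shrink by `radius_decay` and open
#' by `branch_angle`. The generator returns both the rasterized tube
#' union and the exact generating centerline graph (true radius, arc
#' length, tortuosity per branch) for parameter-recovery tests.
#'
#' @param root_position,root_direction numeric length-3, voxel units
#'   `(z, y, x)` (direction need not be normalized).
#' @param generations number of bifurcation levels (0 = single tube).
#' @param radius_root root tube radius, micrometres.
#' @param radius_decay per-generation radius factor in (0, 1].
#' @param segment_length_mean mean branch length, micrometres.
#' @param branch_angle full opening angle between children, degrees.
#' @param wiggle_amplitude dimensionless transverse perturbation
#'   (0 = perfectly straight branches).
#' @param seed integer seed.
#' @export
tree_spec <- function(root_position = NULL, root_direction = c(0, 0, 1),
                      generations = 3, radius_root = 10, radius_decay = 0.8,
                      segment_length_mean = 80, branch_angle = 40,
                      wiggle_amplitude = 0.15, seed = 1) {
  stopifnot(generations >= 0, radius_decay > 0, radius_decay <= 1,
            radius_root > 0, segment_length_mean > 0, wiggle_amplitude >= 0)
  structure(list(root_position = root_position,
                 root_direction = root_direction / sqrt(sum(root_direction^2)),
                 generations = as.integer(generations),
                 radius_root = radius_root, radius_decay = radius_decay,
                 segment_length_mean = segment_length_mean,
                 branch_angle = branch_angle,
                 wiggle_amplitude = wiggle_amplitude, seed = as.integer(seed)),
            class = "tree_spec")
}

# unit vector orthogonal to v (deterministic choice)
orthonormal_pair <- function(v) {
  a <- if (abs(v[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  e1 <- a - sum(a * v) * v
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  list(e1 = e1, e2 = e2)
}

rotate_about <- function(v, axis, angle) {
  axis <- axis / sqrt(sum(axis^2))
  v * cos(angle) +
    c(axis[2] * v[3] - axis[3] * v[2],
      axis[3] * v[1] - axis[1] * v[3],
      axis[1] * v[2] - axis[2] * v[1]) * sin(angle) +
    axis * sum(axis * v) * (1 - cos(angle))
}

# one wiggly branch polyline from p along dir, length L voxels, radius r
branch_polyline <- function(p, dir, L, wiggle, step = 1) {
  n <- max(2, ceiling(L / step))
  on <- orthonormal_pair(dir)
  s <- seq(0, L, length.out = n)
  ph1 <- stats::runif(1, 0, 2 * pi)
  ph2 <- stats::runif(1, 0, 2 * pi)
  nwav <- stats::runif(1, 1, 2)
  amp <- wiggle * L / (2 * pi * nwav)
  off1 <- amp * (sin(2 * pi * nwav * s / L + ph1) - sin(ph1))
  off2 <- amp * (sin(2 * pi * nwav * s / L + ph2) - sin(ph2))
  # taper the offset to zero at both ends so branches meet their parents
  w <- sin(pi * s / L)^2
  pts <- t(p + outer(dir, s)) + (off1 * w) %o% on$e1 + (off2 * w) %o% on$e2
  pts
}

#' Generate a rasterized vessel tree with its ground-truth centerline
#'
#' @param tree a [tree_spec()].
#' @param canvas a [synthetic_spec()] providing shape and voxel size.
#' @return A list with `labels` (a [label_volume()], vessel voxels = 2),
#'   `truth` (tibble of per-branch generation, radius, arc length, chord
#'   length and tortuosity, with the polyline as a list column) and
#'   `clipped` (TRUE when any branch left the canvas and was clipped).
#' @export
generate_vessel_tree <- function(tree, canvas) {
  stopifnot(inherits(tree, "tree_spec"), inherits(canvas, "synthetic_spec"))
  h <- canvas$voxel_size_um
  d <- canvas$shape
  r_vox <- tree$radius_root * tree$radius_decay^tree$generations / h
  if (r_vox < 1.5) {
    stop(sprintf(paste0("smallest branch radius %.2f voxels is below the ",
                        "1.5-voxel resolvability limit"), r_vox))
  }
  root <- tree$root_position
  if (is.null(root)) root <- c(d[1] / 2, d[2] / 2, 4)
  branches <- list()
  with_seed(tree$seed, {
    queue <- list(list(p = root, dir = tree$root_direction, gen = 0L))
    while (length(queue)) {
      b <- queue[[1]]
      queue <- queue[-1]
      L <- tree$segment_length_mean / h * stats::runif(1, 0.8, 1.2)
      r <- tree$radius_root * tree$radius_decay^b$gen / h
      pts <- branch_polyline(b$p, b$dir, L, tree$wiggle_amplitude)
      branches[[length(branches) + 1]] <-
        list(pts = pts, r = r, gen = b$gen)
      if (b$gen < tree$generations) {
        endd <- pts[nrow(pts), ] - pts[nrow(pts) - 1, ]
        endd <- endd / sqrt(sum(endd^2))
        az <- stats::runif(1, 0, 2 * pi)
        on <- orthonormal_pair(endd)
        axis <- cos(az) * on$e1 + sin(az) * on$e2
        half <- tree$branch_angle * pi / 180 / 2
        for (sgn in c(-1, 1)) {
          nd <- rotate_about(endd, axis, sgn * half)
          queue[[length(queue) + 1]] <-
            list(p = pts[nrow(pts), ], dir = nd, gen = b$gen + 1L)
        }
      }
    }
  })
  # rasterize: sweep a ball along each polyline at fine spacing
  all_centers <- NULL
  all_radii <- NULL
  clipped <- FALSE
  for (b in branches) {
    pts <- resample_polyline(b$pts, 0.35)
    if (any(pts < -b$r) || any(sweep(pts, 2, d - 1) > b$r)) clipped <- TRUE
    all_centers <- rbind(all_centers, pts)
    all_radii <- c(all_radii, rep(b$r, nrow(pts)))
  }
  res <- stamp_balls_cpp(d, all_centers, all_radii)
  lab <- array(as.integer(res$mask) * 2L, dim = d)
  labels <- label_volume(lab, h)
  truth <- tibble::tibble(
    branch = seq_along(branches),
    generation = vapply(branches, function(b) b$gen, integer(1)),
    radius_um = vapply(branches, function(b) b$r * h, numeric(1)),
    length_um = vapply(branches, function(b) polyline_length(b$pts) * h,
                       numeric(1)),
    chord_um = vapply(branches, function(b) {
      sqrt(sum((b$pts[nrow(b$pts), ] - b$pts[1, ])^2)) * h
    }, numeric(1)),
    path = lapply(branches, function(b) b$pts)
  )
  truth$tortuosity <- truth$length_um / truth$chord_um
  list(labels = labels, truth = truth, clipped = clipped)
}

polyline_length <- function(pts) {
  if (nrow(pts) < 2) return(0)
  sum(sqrt(rowSums(diff(pts)^2)))
}

# resample a polyline at ~constant spacing (voxel units)
resample_polyline <- function(pts, spacing) {
  seglen <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seglen))
  total <- s[length(s)]
  if (total == 0) return(pts[1, , drop = FALSE])
  ss <- seq(0, total, by = spacing)
  if (ss[length(ss)] < total) ss <- c(ss, total)
  out <- matrix(0, length(ss), 3)
  for (k in 1:3) out[, k] <- stats::approx(s, pts[, k], xout = ss)$y
  out
}

#' Analytic channel fixtures for flow validation
#'
#' @param kind one of `"plane_slab"` (pore slab of thickness
#'   `radius_or_gap` centered in y, flow along x), `"circular_tube"`
#'   (pore cylinder of radius `radius_or_gap` along x), `"empty_box"`
#'   (all pore) or `"blocked_box"` (a solid wall splits the box normal
#'   to x, so no path connects the x faces).
#' @param dims integer `(z, y, x)` extents in voxels.
#' @param radius_or_gap slab gap or tube radius, voxels.
#' @param voxel_size_um voxel edge, micrometres.
#' @return A [label_volume()] (pore = 0, tissue = 1).
#' @export
make_channel_fixture <- function(kind = c("plane_slab", "circular_tube",
                                          "empty_box", "blocked_box"),
                                 dims, radius_or_gap = NULL,
                                 voxel_size_um = 2) {
  kind <- match.arg(kind)
  dims <- as.integer(dims)
  stopifnot(length(dims) == 3)
  lab <- array(1L, dim = dims)
  if (kind %in% c("plane_slab", "circular_tube") &&
      (is.null(radius_or_gap) || radius_or_gap < 8)) {
    stop("`radius_or_gap` must be >= 8 voxels for flow-accuracy fixtures")
  }
  if (kind == "plane_slab") {
    g <- radius_or_gap
    y0 <- floor((dims[2] - g) / 2) + 1
    lab[, y0:(y0 + g - 1), ] <- 0L
  } else if (kind == "circular_tube") {
    r <- radius_or_gap
    cz <- (dims[1] - 1) / 2
    cy <- (dims[2] - 1) / 2
    zz <- (seq_len(dims[1]) - 1) - cz
    yy <- (seq_len(dims[2]) - 1) - cy
    disk <- outer(zz^2, yy^2, `+`) <= r^2
    lab[rep(disk, dims[3])] <- 0L
    dim(lab) <- dims
  } else if (kind == "empty_box") {
    lab[] <- 0L
  } else { # blocked_box: pore everywhere except a full wall at mid-x
    lab[] <- 0L
    lab[, , ceiling(dims[3] / 2)] <- 1L
  }
  label_volume(lab, voxel_size_um)
}

#' Render a label volume as a synthetic grayscale image
#'
#' Per-phase mean intensities, Gaussian blur of given sigma (voxels) and
#' additive white Gaussian noise, in that order; deterministic under
#' `seed`. Emulates the soft-edged, noisy appearance of reconstructed
#' phase-contrast data at the level needed to exercise segmentation
#' fusion (no attempt at fringes or reconstruction artifacts).
#'
#' @param labels a [label_volume()].
#' @param phase_means named numeric vector of per-phase mean intensities
#'   (names matching the legend); must be pairwise distinct.
#' @param blur_sigma Gaussian blur sd in voxels (0 = none).
#' @param noise_sd additive Gaussian noise sd.
#' @param seed integer seed.
#' @return An [image_volume()].
#' @export
render_grayscale <- function(labels, phase_means = c(pore = 0.2, tissue = 0.6,
                                                     vessel = 0.9),
                             blur_sigma = 1, noise_sd = 0.05, seed = 1) {
  stopifnot(is_label_volume(labels))
  if (anyDuplicated(phase_means)) stop("`phase_means` must be distinct")
  img <- array(0, dim = dim(labels$data))
  for (ph in names(phase_means)) {
    if (!ph %in% names(labels$legend)) next
    img[labels$data == labels$legend[[ph]]] <- phase_means[[ph]]
  }
  if (blur_sigma > 0) img <- gaussian_blur3(img, blur_sigma)
  if (noise_sd > 0) {
    with_seed(seed, {
      img <- img + array(stats::rnorm(length(img), 0, noise_sd), dim = dim(img))
    })
  }
  image_volume(img, labels$voxel_size_um)
}
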