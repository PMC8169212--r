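#' Slice predictors
#'
#' A slice predictor is a pure function mapping a 2D grayscale matrix to
#' a binary mask of the same shape. `threshold_predictor()` builds the
#' global-threshold predictor used as the test oracle.
#' `noisy_predictor()` wraps a predictor with deterministic pseudo-random
#' label flips: the flip pattern is derived from the slice content (so
#' the predictor stays pure) and differs between views, emulating the
#' view-dependent errors of a 2D model applied slice-wise to a 3D volume.
#'
#' @param threshold intensity cut; pixels `>= threshold` become 1.
#' @return A function `(matrix) -> binary matrix`.
#' @export
threshold_predictor <- function(threshold = 0.5) {
  force(threshold)
  function(slice) {
    out <- (slice >= threshold) * 1L
    dim(out) <- dim(slice)
    out
  }
}

#' @rdname threshold_predictor
#' @param predictor predictor to perturb.
#' @param flip_prob per-pixel probability of flipping the predicted label.
#' @param salt integer mixed into the content-derived seed.
#' @export
noisy_predictor <- function(predictor = threshold_predictor(),
                            flip_prob = 0.05, salt = 0) {
  force(predictor); force(flip_prob); force(salt)
  function(slice) {
    m <- predictor(slice)
    # content hash -> deterministic, view-dependent flip pattern
    key <- sum(abs(slice) * seq_along(slice) %% 97) * 1e4 + salt
    seed <- as.integer(round(key) %% 2147483647)
    with_seed(seed, {
      flips <- stats::runif(length(m)) < flip_prob
      m[flips] <- 1L - m[flips]
    })
    m
  }
}

# rotate a (z,y,x) volume by k*90 degrees counterclockwise about z.
# Requires square (y,x) extent; rotations on the integer grid are lossless.
rot90_vol <- function(arr, k) {
  k <- k %% 4
  if (k == 0) return(arr)
  for (i in seq_len(k)) {
    arr <- aperm(arr, c(1, 3, 2))          # transpose (y,x)
    arr <- arr[, dim(arr)[2]:1, , drop = FALSE] # reverse new y
  }
  arr
}

# apply a slice predictor along one plane of a volume
predict_plane <- function(arr, predictor, plane, pass_id) {
  d <- dim(arr)
  out <- array(0L, dim = d)
  n_slices <- switch(plane, xy = d[1], xz = d[2], yz = d[3])
  for (s in seq_len(n_slices)) {
    sl <- switch(plane,
                 xy = array(arr[s, , ], d[2:3]),
                 xz = array(arr[, s, ], d[c(1, 3)]),
                 yz = array(arr[, , s], d[1:2]))
    pr <- predictor(sl)
    if (!identical(dim(pr), dim(sl))) {
      stop(sprintf("predictor output shape mismatch in pass %s, slice %d",
                   pass_id, s))
    }
    if (!all(pr %in% c(0, 1))) {
      stop(sprintf("predictor output not binary in pass %s, slice %d",
                   pass_id, s))
    }
    switch(plane,
           xy = { out[s, , ] <- pr },
           xz = { out[, s, ] <- pr },
           yz = { out[, , s] <- pr })
  }
  out
}

#' Multi-view 2.5D prediction fusion
#'
#' The volume is sliced into stacks parallel to the xy, xz and yz planes
#' and each slice is segmented by the injected 2D predictor; the three
#' reassembled 3D masks are computed for each of four rotations (0, 90,
#' 180, 270 degrees about the z axis, the fourfold symmetry axis), every
#' mask is rotated back into the reference frame, and the 12 aligned
#' binary masks are summed voxelwise into an agreement-count volume.
#' Non-square (y, x) extents are zero-padded to square before rotating
#' and un-padded afterwards.
#'
#' @param vol an [image_volume()] (at least 2 voxels per axis).
#' @param predictor a slice predictor, e.g. [threshold_predictor()].
#' @return A `vote_volume`: list with `data` (integer counts in 0..12),
#'   `provenance` (tibble of the 12 passes) and `voxel_size_um`.
#' @export
multi_view_predict <- function(vol, predictor) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$data)
  if (any(d < 2)) stop("volume must be at least 2 voxels per axis")
  n <- max(d[2], d[3])
  padded <- d[2] != d[3]
  arr <- vol$data
  if (padded) {
    big <- array(0, dim = c(d[1], n, n))
    big[, seq_len(d[2]), seq_len(d[3])] <- arr
    arr <- big
  }
  votes <- array(0L, dim = dim(arr))
  prov <- list()
  for (k in 0:3) {
    rot <- rot90_vol(arr, k)
    for (plane in c("xy", "xz", "yz")) {
      pass_id <- sprintf("rot%d_%s", 90 * k, plane)
      mask <- predict_plane(rot, predictor, plane, pass_id)
      votes <- votes + rot90_vol(mask, (4 - k) %% 4)
      prov[[length(prov) + 1]] <-
        tibble::tibble(pass = length(prov) + 1L, rotation_deg = 90L * k,
                       plane = plane)
    }
  }
  if (padded) votes <- votes[, seq_len(d[2]), seq_len(d[3]), drop = FALSE]
  structure(list(data = votes, provenance = dplyr::bind_rows(prov),
                 voxel_size_um = vol$voxel_size_um),
            class = "vote_volume")
}

#' Threshold an agreement-count volume into a binary segmentation
#'
#' @param votes a `vote_volume` from [multi_view_predict()].
#' @param min_agreement integer in 1..12, or a preset name: `"blood"`
#'   (6 of 12, used for the maternal/fetal blood volumes) or `"vessels"`
#'   (9 of 12, used for the vessel lumen).
#' @return A binary [label_volume()] (0/1).
#' @export
threshold_votes <- function(votes, min_agreement = "blood") {
  stopifnot(inherits(votes, "vote_volume"))
  if (is.character(min_agreement)) {
    min_agreement <- switch(match.arg(min_agreement, c("blood", "vessels")),
                            blood = 6L, vessels = 9L)
  }
  min_agreement <- as.integer(min_agreement)
  if (min_agreement < 1 || min_agreement > 12) {
    stop("`min_agreement` must be in 1..12")
  }
  label_volume(array(as.integer(votes$data >= min_agreement),
                     dim = dim(votes$data)),
               votes$voxel_size_um)
}

as_binary_array <- function(x) {
  a <- vol_data(x)
  if (is.logical(a)) a <- a * 1L
  if (!all(a %in% c(0, 1))) stop("mask must be binary")
  a
}

#' Overlap metrics between binary segmentations
#'
#' `dice()` computes the Sorensen-Dice coefficient
#' `2|M * U| / (|M| + |U|)`; `iou()` the Jaccard index
#' `|M * U| / |M + U - M*U|`. When both masks are empty the score is
#' defined as 1 (identity of empties). With `by_slice = TRUE` the score
#' is computed per z-slice.
#'
#' @param m,u binary arrays or volumes of identical shape.
#' @param by_slice compute one score per z-slice instead of a global one.
#' @return A fraction in `[0, 1]`, or a numeric vector when `by_slice`.
#' @export
dice <- function(m, u, by_slice = FALSE) {
  m <- as_binary_array(m)
  u <- as_binary_array(u)
  if (!identical(dim(m), dim(u))) stop("mask shapes differ")
  if (by_slice) {
    vapply(seq_len(dim(m)[1]), function(k) {
      dice_scalar(m[k, , ], u[k, , ])
    }, numeric(1))
  } else {
    dice_scalar(m, u)
  }
}

dice_scalar <- function(m, u) {
  inter <- sum(m & u)
  denom <- sum(m) + sum(u)
  if (denom == 0) 1 else 2 * inter / denom
}

#' @rdname dice
#' @export
iou <- function(m, u, by_slice = FALSE) {
  m <- as_binary_array(m)
  u <- as_binary_array(u)
  if (!identical(dim(m), dim(u))) stop("mask shapes differ")
  f <- function(a, b) {
    un <- sum(a | b)
    if (un == 0) 1 else sum(a & b) / un
  }
  if (by_slice) {
    vapply(seq_len(dim(m)[1]), function(k) f(m[k, , ], u[k, , ]), numeric(1))
  } else {
    f(m, u)
  }
}

#' Per-slice area fraction of a phase
#'
#' @param labels a [label_volume()] or integer array.
#' @param phase phase value or legend name.
#' @return A tibble with `slice` (0-based z index) and `area_fraction`;
#'   the mean over slices equals the phase volume fraction exactly.
#' @export
area_fraction_per_slice <- function(labels, phase) {
  mk <- phase_mask(labels, phase)
  d <- dim(mk)
  tibble::tibble(slice = seq_len(d[1]) - 1L,
                 area_fraction = apply(mk, 1, mean))
}
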