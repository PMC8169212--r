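#' Volume containers
#'
#' `image_volume()` wraps a 3D grayscale array; `label_volume()` wraps a 3D
#' integer phase map with the legend `0 = pore/IVS`, `1 = tissue`,
#' `2 = vessel lumen`. Both carry an isotropic voxel size in micrometres.
#'
#' Axis convention: arrays are indexed `[z, y, x]`, i.e. `dim(data)` is
#' `c(nz, ny, nx)` and `vol$data[k, , ]` is the k-th z-slice as a `(y, x)`
#' matrix. Voxel offsets in function arguments (e.g. [crop_roi()]) are
#' 0-based so that an offset of 0 means "start at the first voxel".
#'
#' @param data 3D numeric (image) or integer-valued (label) array.
#' @param voxel_size_um isotropic voxel edge length, micrometres (> 0).
#' @return An object of class `image_volume` or `label_volume`.
#' @examples
#' v <- label_volume(array(0L, c(8, 8, 8)), voxel_size_um = 2)
#' dim(v$data)
#' @export
image_volume <- function(data, voxel_size_um) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1 ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0) {
    stop("`voxel_size_um` must be a single positive number")
  }
  if (any(!is.finite(data))) stop("image data must be finite")
  structure(list(data = data, voxel_size_um = voxel_size_um),
            class = c("image_volume", "mt_volume"))
}

#' @rdname image_volume
#' @param legend named integer vector mapping phase names to label values.
#' @export
label_volume <- function(data, voxel_size_um,
                         legend = c(pore = 0L, tissue = 1L, vessel = 2L)) {
  stopifnot(is.array(data), length(dim(data)) == 3)
  if (!is.numeric(voxel_size_um) || length(voxel_size_um) != 1 ||
      !is.finite(voxel_size_um) || voxel_size_um <= 0) {
    stop("`voxel_size_um` must be a single positive number")
  }
  storage.mode(data) <- "integer"
  bad <- setdiff(unique(as.vector(data)), unname(legend))
  if (length(bad)) {
    stop("labels outside legend: ", paste(bad, collapse = ", "))
  }
  structure(list(data = data, voxel_size_um = voxel_size_um, legend = legend),
            class = c("label_volume", "mt_volume"))
}

#' @export
print.mt_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %d x %d x %d voxels (z,y,x) @ %.4g um/voxel\n",
              class(x)[1], d[1], d[2], d[3], x$voxel_size_um))
  if (inherits(x, "label_volume")) {
    tab <- table(factor(as.vector(x$data), levels = unname(x$legend)))
    frac <- as.numeric(tab) / length(x$data)
    cat("  phase fractions:",
        paste(sprintf("%s=%.3f", names(x$legend), frac), collapse = ", "), "\n")
  }
  invisible(x)
}

is_label_volume <- function(x) inherits(x, "label_volume")

# Accept a label_volume or a bare array; return the array.
vol_data <- function(x) {
  if (inherits(x, "mt_volume")) x$data else x
}

# phase mask helper: phase given by name or integer value
phase_mask <- function(labels, phase) {
  if (is_label_volume(labels) && is.character(phase)) {
    phase <- labels$legend[[phase]]
  }
  vol_data(labels) == phase
}

#' Crop a rectangular ROI from a volume
#'
#' Half-open interval semantics: the ROI covers voxels
#' `origin + 1 .. origin + shape` in each axis (`origin` is a 0-based
#' offset in `(z, y, x)` order).
#'
#' @param vol an `image_volume` or `label_volume`.
#' @param origin integer vector of 3 offsets (0-based), `(z, y, x)`.
#' @param shape integer vector of 3 positive extents, `(z, y, x)`.
#' @return A volume of the same class; voxel size is preserved.
#' @export
crop_roi <- function(vol, origin, shape) {
  stopifnot(inherits(vol, "mt_volume"), length(origin) == 3, length(shape) == 3)
  origin <- as.integer(origin)
  shape <- as.integer(shape)
  if (any(shape <= 0)) stop("`shape` must be positive in every axis")
  d <- dim(vol$data)
  for (ax in 1:3) {
    if (origin[ax] < 0 || origin[ax] + shape[ax] > d[ax]) {
      stop(sprintf("ROI out of bounds on axis %s (%s): [%d, %d) outside [0, %d)",
                   ax, c("z", "y", "x")[ax], origin[ax],
                   origin[ax] + shape[ax], d[ax]))
    }
  }
  out <- vol
  out$data <- vol$data[origin[1] + seq_len(shape[1]),
                       origin[2] + seq_len(shape[2]),
                       origin[3] + seq_len(shape[3]), drop = FALSE]
  out
}

#' Integer down-sampling by block aggregation
#'
#' Grayscale volumes are block-averaged; label volumes take the majority
#' vote in each `factor^3` block, with ties resolved to the lower label
#' (deterministic). Trailing partial blocks are dropped with a message.
#' The voxel size is multiplied by `factor`.
#'
#' @param vol an `image_volume` or `label_volume`.
#' @param factor integer >= 2.
#' @return A volume of the same class.
#' @export
downsample <- function(vol, factor) {
  stopifnot(inherits(vol, "mt_volume"))
  factor <- as.integer(factor)
  if (factor < 2) stop("`factor` must be >= 2")
  d <- dim(vol$data)
  nd <- d %/% factor
  if (any(nd == 0)) stop("volume smaller than one block")
  if (any(d %% factor != 0)) {
    message(sprintf("downsample: dropping trailing partial blocks (%s -> %s)",
                    paste(d, collapse = "x"),
                    paste(nd * factor, collapse = "x")))
  }
  trimmed <- vol$data[seq_len(nd[1] * factor), seq_len(nd[2] * factor),
                      seq_len(nd[3] * factor), drop = FALSE]
  out <- vol
  out$voxel_size_um <- vol$voxel_size_um * factor
  if (is_label_volume(vol)) {
    vals <- sort(unique(as.vector(trimmed)))
    counts <- lapply(vals, function(v) block_sum(trimmed == v, factor))
    # majority vote; ties go to the lower label (vals is ascending and
    # max.col(ties.method = "first") picks the first maximum)
    cnt <- vapply(counts, as.vector, numeric(length(counts[[1]])))
    pick <- max.col(cnt, ties.method = "first")
    out$data <- array(as.integer(vals[pick]), dim = nd)
  } else {
    out$data <- block_sum(trimmed, factor) / factor^3
  }
  out
}

# sum over non-overlapping factor^3 blocks; returns array dim d %/% factor
block_sum <- function(arr, factor) {
  d <- dim(arr)
  nd <- d %/% factor
  x <- array(as.numeric(arr), dim = c(factor, nd[1], factor, nd[2], factor, nd[3]))
  colSums(aperm(x, c(1, 3, 5, 2, 4, 6)), dims = 3)
}

#' Read and write volumes as multipage TIFF with a JSON sidecar
#'
#' `write_volume()` stores the z-slices of a volume as a multipage TIFF
#' (8-bit for labels, 32-bit float for grayscale) and a `<path>.json`
#' sidecar holding the voxel size, the kind of volume and the phase
#' legend. `read_volume()` reverses it losslessly. A TIFF without sidecar
#' is refused unless `voxel_size_um` is given explicitly.
#'
#' @param vol volume to write.
#' @param path TIFF file path.
#' @return `read_volume()` returns an `image_volume` or `label_volume`.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "mt_volume"))
  d <- dim(vol$data)
  pages <- lapply(seq_len(d[1]), function(k) {
    m <- vol$data[k, , , drop = TRUE]
    dim(m) <- d[2:3]
    m
  })
  if (is_label_volume(vol)) {
    if (max(vol$data) > 255) stop("labels exceed 8-bit range")
    tiff::writeTIFF(lapply(pages, function(m) m / 255), path,
                    bits.per.sample = 8)
    kind <- "label"
  } else {
    tiff::writeTIFF(lapply(pages, function(m) {
      storage.mode(m) <- "double"
      m
    }), path, bits.per.sample = 32)
    kind <- "image"
  }
  sidecar <- list(voxel_size_um = vol$voxel_size_um, kind = kind,
                  dim_zyx = d)
  if (is_label_volume(vol)) sidecar$phase_legend <- as.list(vol$legend)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_volume
#' @param voxel_size_um explicit voxel size override when no sidecar exists.
#' @export
read_volume <- function(path, voxel_size_um = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  sidecar_path <- paste0(path, ".json")
  sidecar <- NULL
  if (file.exists(sidecar_path)) {
    sidecar <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  }
  if (is.null(sidecar) && is.null(voxel_size_um)) {
    stop("no JSON sidecar with voxel size next to ", path,
         "; pass `voxel_size_um` explicitly to override")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- c(length(pages), dim(pages[[1]]))
  arr <- array(0, dim = d)
  for (k in seq_along(pages)) arr[k, , ] <- pages[[k]]
  vs <- if (!is.null(voxel_size_um)) voxel_size_um else sidecar$voxel_size_um
  kind <- if (!is.null(sidecar)) sidecar$kind else "image"
  if (identical(kind, "label")) {
    lab <- array(as.integer(round(arr * 255)), dim = d)
    legend <- c(pore = 0L, tissue = 1L, vessel = 2L)
    if (!is.null(sidecar$phase_legend)) {
      legend <- vapply(sidecar$phase_legend, as.integer, integer(1))
    }
    label_volume(lab, vs, legend = legend)
  } else {
    image_volume(arr, vs)
  }
}
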