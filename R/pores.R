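#' Partition the pore phase into individual pores
#'
#' Marker-controlled watershed on the negated Euclidean distance
#' transform of the pore phase: the EDT is Gaussian-smoothed, its local
#' maxima (with a minimum peak separation of `max(2, smoothing_sigma)`
#' voxels) become basin markers, and priority flooding assigns every
#' pore voxel to exactly one region. Region adjacency later uses
#' 6-connectivity, so a throat is a shared voxel face.
#'
#' @param labels a [label_volume()] or integer/logical array (pore = 0
#'   or TRUE for a logical mask).
#' @param phase phase treated as pore space.
#' @param smoothing_sigma Gaussian sd (voxels) applied to the EDT before
#'   peak picking; larger values suppress over-segmentation.
#' @param voxel_size_um voxel size for a bare array.
#' @param largest_component restrict the analysis to the largest
#'   6-connected component of the pore phase (drops isolated pockets at
#'   grain triple-junctions, which otherwise dominate the small end of
#'   the pore-size distribution).
#' @return A `pore_regions` object: `regions` (integer array, 0 outside
#'   the pore phase), `edt_um` (unsmoothed distance map of the pore
#'   phase), `n_regions`, `voxel_size_um`.
#' @export
separate_pores <- function(labels, phase = "pore", smoothing_sigma = 2,
                           voxel_size_um = NULL, largest_component = FALSE) {
  if (is_label_volume(labels)) {
    mk <- phase_mask(labels, phase)
    h <- labels$voxel_size_um
  } else if (is.logical(labels)) {
    mk <- labels
    h <- voxel_size_um %||% stop("`voxel_size_um` required for a bare array")
  } else {
    mk <- labels == 0
    h <- voxel_size_um %||% stop("`voxel_size_um` required for a bare array")
  }
  if (!any(mk)) stop("pore phase is empty")
  d <- dim(mk)
  if (largest_component) {
    cc <- array(label_components_cpp(as.vector(mk), d, 6L), dim = d)
    tb <- tabulate(cc)
    mk <- cc == which.max(tb)
  }
  # distance in voxels; outside the domain continues the pore phase so
  # boundary pores are not artificially shallow
  edt_vox <- sqrt(array(edt3d_sq_cpp(as.vector(mk), d), dim = d))
  edt_vox[edt_vox > 1e9] <- max(d)  # fully-pore lines: cap at domain scale
  sm <- gaussian_blur3(edt_vox, smoothing_sigma)
  sm[!mk] <- 0
  peaks <- local_maxima_cpp(as.vector(sm), as.vector(mk), d)
  sep <- max(2, smoothing_sigma)
  peaks <- suppress_peaks(peaks, sm[peaks], d, sep)
  markers <- array(0L, dim = d)
  markers[peaks] <- seq_along(peaks)
  regions <- array(watershed_cpp(as.vector(-sm), as.vector(markers),
                                 as.vector(mk), d), dim = d)
  # small components can lose their only peak to suppression by a nearby
  # peak in a different component; label each such orphan as its own pore
  orphan <- mk & regions == 0L
  if (any(orphan)) {
    oc <- array(label_components_cpp(as.vector(orphan), d, 6L), dim = d)
    regions[orphan] <- length(peaks) + oc[orphan]
    oidx <- which(orphan)
    oids <- oc[oidx]
    ord <- order(oids, oidx)
    peaks <- c(peaks, oidx[ord][!duplicated(oids[ord])])
  }
  stopifnot(sum(regions > 0) == sum(mk))  # exact partition of pore phase
  structure(list(regions = regions, edt_um = edt_vox * h,
                 n_regions = length(peaks), voxel_size_um = h, dim = d),
            class = "pore_regions")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# greedy minimum-separation suppression via a spatial grid hash
suppress_peaks <- function(peaks, values, d, sep) {
  if (!length(peaks)) return(peaks)
  co <- arrayInd(peaks, d)
  ord <- order(-values, peaks)
  cell <- floor(co / sep)
  keykeep <- new.env(hash = TRUE)
  kept <- logical(length(peaks))
  for (i in ord) {
    cz <- cell[i, 1]; cy <- cell[i, 2]; cx <- cell[i, 3]
    clash <- FALSE
    for (az in (cz - 1):(cz + 1)) {
      for (ay in (cy - 1):(cy + 1)) {
        for (ax in (cx - 1):(cx + 1)) {
          key <- paste(az, ay, ax, sep = "_")
          pts <- keykeep[[key]]
          if (!is.null(pts)) {
            dd <- sqrt(colSums((t(co[pts, , drop = FALSE]) - co[i, ])^2))
            if (any(dd < sep)) {
              clash <- TRUE
              break
            }
          }
        }
        if (clash) break
      }
      if (clash) break
    }
    if (!clash) {
      kept[i] <- TRUE
      key <- paste(cz, cy, cx, sep = "_")
      keykeep[[key]] <- c(keykeep[[key]], i)
    }
  }
  peaks[kept]
}

#' Build the ball-and-stick pore-throat network
#'
#' Each pore is represented by the maximal inscribed sphere of its
#' watershed region (center at the EDT maximum, diameter twice the EDT
#' there); a throat exists wherever two regions share a 6-connected
#' voxel face, with diameter twice the largest pore-phase EDT over the
#' interface voxels and length the Euclidean distance between the two
#' pore centers (center-to-center).
#'
#' @param regions a `pore_regions` object from [separate_pores()].
#' @return A `pore_network`: `pores` tibble (id, center, diameter_um,
#'   n_voxels, touches_boundary and per-face flags, coordination) and
#'   `throats` tibble (pore_a, pore_b, diameter_um, length_um, n_faces).
#' @export
build_pore_network <- function(regions) {
  stopifnot(inherits(regions, "pore_regions"))
  reg <- regions$regions
  d <- regions$dim
  h <- regions$voxel_size_um
  edt <- regions$edt_um
  inpore <- which(reg > 0)
  rid <- reg[inpore]
  ev <- edt[inpore]
  # per-region EDT maximum (first occurrence for determinism)
  ord <- order(rid, -ev, inpore)
  first <- !duplicated(rid[ord])
  max_idx <- inpore[ord][first]
  max_rid <- rid[ord][first]
  co <- arrayInd(max_idx, d) - 1
  nvox <- tabulate(rid, nbins = max(rid))
  face_flags <- function(axis, low) {
    sel <- switch(axis,
                  z = if (low) reg[1, , ] else reg[d[1], , ],
                  y = if (low) reg[, 1, ] else reg[, d[2], ],
                  x = if (low) reg[, , 1] else reg[, , d[3]])
    tabulate(sel[sel > 0], nbins = max(rid)) > 0
  }
  flags <- list(z_lo = face_flags("z", TRUE), z_hi = face_flags("z", FALSE),
                y_lo = face_flags("y", TRUE), y_hi = face_flags("y", FALSE),
                x_lo = face_flags("x", TRUE), x_hi = face_flags("x", FALSE))
  pores <- tibble::tibble(
    pore = max_rid,
    z = co[, 1], y = co[, 2], x = co[, 3],
    diameter_um = 2 * edt[max_idx],
    n_voxels = nvox[max_rid],
    z_lo = flags$z_lo[max_rid], z_hi = flags$z_hi[max_rid],
    y_lo = flags$y_lo[max_rid], y_hi = flags$y_hi[max_rid],
    x_lo = flags$x_lo[max_rid], x_hi = flags$x_hi[max_rid])
  pores$touches_boundary <- pores$z_lo | pores$z_hi | pores$y_lo |
    pores$y_hi | pores$x_lo | pores$x_hi
  pores <- pores[order(pores$pore), ]
  # throats: 6-connected face adjacencies between distinct regions
  pair_a <- integer(0); pair_b <- integer(0); pair_e <- numeric(0)
  for (ax in 1:3) {
    n_ax <- d[ax]
    idx_a <- switch(ax, reg[-n_ax, , , drop = FALSE],
                    reg[, -n_ax, , drop = FALSE],
                    reg[, , -n_ax, drop = FALSE])
    idx_b <- switch(ax, reg[-1, , , drop = FALSE],
                    reg[, -1, , drop = FALSE],
                    reg[, , -1, drop = FALSE])
    ea <- switch(ax, edt[-n_ax, , , drop = FALSE],
                 edt[, -n_ax, , drop = FALSE],
                 edt[, , -n_ax, drop = FALSE])
    eb <- switch(ax, edt[-1, , , drop = FALSE],
                 edt[, -1, , drop = FALSE],
                 edt[, , -1, drop = FALSE])
    sel <- idx_a > 0 & idx_b > 0 & idx_a != idx_b
    if (any(sel)) {
      a <- pmin(idx_a[sel], idx_b[sel])
      b <- pmax(idx_a[sel], idx_b[sel])
      pair_a <- c(pair_a, a)
      pair_b <- c(pair_b, b)
      pair_e <- c(pair_e, pmax(ea[sel], eb[sel]))
    }
  }
  if (length(pair_a)) {
    key <- paste0(pair_a, "_", pair_b)
    agg_max <- tapply(pair_e, key, max)
    agg_n <- tapply(pair_e, key, length)
    ks <- strsplit(names(agg_max), "_", fixed = TRUE)
    ta <- vapply(ks, function(k) as.integer(k[1]), integer(1))
    tb <- vapply(ks, function(k) as.integer(k[2]), integer(1))
    ca <- as.matrix(pores[match(ta, pores$pore), c("z", "y", "x")])
    cb <- as.matrix(pores[match(tb, pores$pore), c("z", "y", "x")])
    throats <- tibble::tibble(
      pore_a = ta, pore_b = tb,
      diameter_um = 2 * as.numeric(agg_max),
      length_um = sqrt(rowSums((ca - cb)^2)) * h,
      n_faces = as.integer(agg_n))
    throats <- throats[order(throats$pore_a, throats$pore_b), ]
  } else {
    throats <- tibble::tibble(pore_a = integer(0), pore_b = integer(0),
                              diameter_um = numeric(0),
                              length_um = numeric(0), n_faces = integer(0))
  }
  coord <- tabulate(c(throats$pore_a, throats$pore_b),
                    nbins = max(pores$pore))
  pores$coordination <- coord[pores$pore]
  structure(list(pores = pores, throats = throats, voxel_size_um = h,
                 dim = d), class = "pore_network")
}

#' @export
print.pore_network <- function(x, ...) {
  cat(sprintf("<pore_network> %d pores, %d throats\n",
              nrow(x$pores), nrow(x$throats)))
  if (nrow(x$pores)) {
    cat(sprintf("  median pore diameter %.1f um, median coordination %g\n",
                stats::median(x$pores$diameter_um),
                stats::median(x$pores$coordination)))
  }
  invisible(x)
}

#' Assemble a pore network from bare tables
#'
#' Convenience constructor used for algorithmic tests and for networks
#' coming from other tools.
#'
#' @param pores tibble with at least `pore`, `diameter_um`,
#'   `touches_boundary` (and optionally centers).
#' @param throats tibble with `pore_a`, `pore_b`, `diameter_um`.
#' @param voxel_size_um voxel size tag carried along.
#' @export
pore_network <- function(pores, throats, voxel_size_um = 1) {
  pores <- tibble::as_tibble(pores)
  throats <- tibble::as_tibble(throats)
  stopifnot(all(c("pore", "diameter_um", "touches_boundary") %in%
                  names(pores)),
            all(c("pore_a", "pore_b", "diameter_um") %in% names(throats)))
  if (any(throats$pore_a == throats$pore_b)) {
    stop("throats must connect distinct pores")
  }
  coord <- tabulate(c(throats$pore_a, throats$pore_b),
                    nbins = max(pores$pore))
  pores$coordination <- coord[pores$pore]
  structure(list(pores = pores, throats = throats,
                 voxel_size_um = voxel_size_um, dim = NULL),
            class = "pore_network")
}

#' Critical pore-throat diameter for connectivity to the periphery
#'
#' The largest diameter d* such that a path of pores and throats, all
#' with diameter >= d*, connects the source pore to any pore touching
#' the domain boundary: a maximin (bottleneck-path) statistic. Computed
#' by inserting elements in descending diameter order into a union-find
#' structure until the source joins the boundary.
#'
#' @param net a `pore_network`.
#' @param source a pore id, or `"random_central"` to draw a pore whose
#'   center lies in the central eighth of the domain (needs centers and
#'   `dim`), under `seed`.
#' @param seed integer seed for the random source draw.
#' @return d* in micrometres; 0 (with attribute `isolated = TRUE`) when
#'   the source never connects.
#' @export
critical_percolation_diameter <- function(net, source = "random_central",
                                          seed = NULL) {
  stopifnot(inherits(net, "pore_network"))
  if (!nrow(net$pores)) stop("empty network")
  if (!any(net$pores$touches_boundary)) {
    stop("no boundary-touching pore in the network")
  }
  if (identical(source, "random_central")) {
    if (is.null(net$dim)) stop("random_central needs a voxel-derived network")
    d <- net$dim
    central <- net$pores$z >= d[1] / 4 & net$pores$z < 3 * d[1] / 4 &
      net$pores$y >= d[2] / 4 & net$pores$y < 3 * d[2] / 4 &
      net$pores$x >= d[3] / 4 & net$pores$x < 3 * d[3] / 4
    cand <- net$pores$pore[central]
    if (!length(cand)) stop("no pore center lies in the central eighth")
    source <- with_seed(seed, cand[sample.int(length(cand), 1)])
  }
  if (!source %in% net$pores$pore) stop("unknown source pore id")
  np <- max(net$pores$pore)
  # union-find over pores + a virtual boundary node (np + 1)
  parent <- seq_len(np + 1L)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  virt <- np + 1L
  # event list: pores and throats, descending diameter; at equal diameter
  # activation order does not matter for connectivity at that threshold,
  # but we process pores first so pending throats can resolve
  ev_type <- c(rep(0L, nrow(net$pores)), rep(1L, nrow(net$throats)))
  ev_a <- c(net$pores$pore, net$throats$pore_a)
  ev_b <- c(rep(0L, nrow(net$pores)), net$throats$pore_b)
  ev_d <- c(net$pores$diameter_um, net$throats$diameter_um)
  ev_bnd <- c(net$pores$touches_boundary, rep(FALSE, nrow(net$throats)))
  o <- order(-ev_d, ev_type, ev_a, ev_b)
  ev_type <- ev_type[o]; ev_a <- ev_a[o]; ev_b <- ev_b[o]
  ev_d <- ev_d[o]; ev_bnd <- ev_bnd[o]
  active <- logical(np)
  pending <- vector("list", np)
  src <- as.integer(source)
  connected <- function() find(src) == find(virt)
  unify <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[ri] <<- rj
  }
  for (r in seq_along(ev_type)) {
    if (ev_type[r] == 0L) {
      p <- ev_a[r]
      active[p] <- TRUE
      if (ev_bnd[r]) unify(p, virt)
      pp <- pending[[p]]
      if (length(pp)) {
        for (t in pp) {
          if (active[t]) unify(p, t)
        }
        pending[p] <- list(pp[!active[pp]])
      }
    } else {
      a <- ev_a[r]; b <- ev_b[r]
      if (active[a] && active[b]) {
        unify(a, b)
      } else {
        if (!active[a]) pending[[a]] <- c(pending[[a]], b)
        if (!active[b]) pending[[b]] <- c(pending[[b]], a)
      }
    }
    if (active[src] && connected()) {
      out <- ev_d[r]
      attr(out, "source") <- src
      return(out)
    }
  }
  out <- 0
  attr(out, "isolated") <- TRUE
  attr(out, "source") <- src
  out
}

#' Median / IQR summary of a pore network
#'
#' @param net a `pore_network`.
#' @param d_star optional critical percolation diameter; when given (and
#'   the median pore diameter is defined) the summary carries the ratio
#'   `d_star / median pore diameter` as attribute
#'   `d_star_to_median_pore`.
#' @return A tibble with one row per metric.
#' @export
summarize_pores <- function(net, d_star = NULL) {
  stopifnot(inherits(net, "pore_network"))
  if (!nrow(net$pores)) stop("empty network")
  mets <- list(pore_diameter_um = net$pores$diameter_um,
               throat_diameter_um = net$throats$diameter_um,
               throat_length_um = net$throats$length_um,
               coordination = as.numeric(net$pores$coordination))
  out <- purrr::map_dfr(names(mets), function(m) {
    x <- mets[[m]]
    x <- x[is.finite(x)]
    if (!length(x)) {
      return(tibble::tibble(metric = m, median = NA_real_, q25 = NA_real_,
                            q75 = NA_real_, n = 0L))
    }
    q <- quantile_iqr(x)
    tibble::tibble(metric = m, median = q[["median"]], q25 = q[["q25"]],
                   q75 = q[["q75"]], n = length(x))
  })
  if (!is.null(d_star)) {
    med <- out$median[out$metric == "pore_diameter_um"]
    if (is.finite(med) && med > 0) {
      attr(out, "d_star_to_median_pore") <- as.numeric(d_star) / med
    }
  }
  out
}

#' Export a pore network as CSV tables and a JSON document
#'
#' @param net a `pore_network`.
#' @param dir output directory (created if missing).
#' @export
write_pore_network <- function(net, dir) {
  stopifnot(inherits(net, "pore_network"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  utils::write.csv(net$pores, file.path(dir, "pores.csv"), row.names = FALSE)
  utils::write.csv(net$throats, file.path(dir, "throats.csv"),
                   row.names = FALSE)
  jsonlite::write_json(list(pores = net$pores, throats = net$throats,
                            voxel_size_um = net$voxel_size_um),
                       file.path(dir, "network.json"), digits = NA)
  invisible(dir)
}
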