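#' Define a Stokes flow problem on the pore phase
#'
#' Steady incompressible Stokes flow is driven by a fixed pressure drop
#' between the two domain faces normal to `direction`; the four lateral
#' faces are impermeable (zero normal velocity, by default with free
#' tangential slip), and a no-slip condition holds on every fluid-solid
#' interface.
#'
#' @param geometry a [label_volume()]; the pore phase (label 0) is the
#'   fluid.
#' @param direction flow axis, one of `"x"`, `"y"`, `"z"`.
#' @param pressure_drop applied pressure drop in Pa; the default scales
#'   a physiological-range gradient of 10 Pa/mm to the domain length.
#' @param viscosity dynamic viscosity, Pa s (default 0.003, whole blood).
#' @param lateral lateral-wall tangential condition, `"slip"` (default)
#'   or `"noslip"`.
#' @return A `flow_problem` list.
#' @export
flow_problem <- function(geometry, direction = c("y", "x", "z"),
                         pressure_drop = NULL, viscosity = 0.003,
                         lateral = c("slip", "noslip")) {
  stopifnot(is_label_volume(geometry))
  direction <- match.arg(direction)
  lateral <- match.arg(lateral)
  d <- dim(geometry$data)
  n_flow <- switch(direction, x = d[3], y = d[2], z = d[1])
  if (is.null(pressure_drop)) {
    pressure_drop <- 0.01 * n_flow * geometry$voxel_size_um  # 10 Pa/mm
  }
  if (pressure_drop <= 0) stop("`pressure_drop` must be positive")
  if (viscosity <= 0) stop("`viscosity` must be positive")
  structure(list(geometry = geometry, direction = direction,
                 pressure_drop = pressure_drop, viscosity = viscosity,
                 lateral = lateral),
            class = "flow_problem")
}

# permutation taking (z,y,x) arrays to a frame whose 3rd axis is the flow
# direction; perm_back inverts it
flow_perm <- function(direction) {
  switch(direction,
         x = list(fwd = c(1, 2, 3), bwd = c(1, 2, 3)),
         y = list(fwd = c(1, 3, 2), bwd = c(1, 3, 2)),
         z = list(fwd = c(2, 3, 1), bwd = c(3, 1, 2)))
}

#' Solve Stokes flow on the voxel grid
#'
#' Marker-and-cell staggered discretization: velocity components live on
#' cell faces, pressure at cell centers of the fluid phase. The viscous
#' operator is the standard 7-point Laplacian per component with ghost
#' reflection at no-slip walls; the discrete saddle-point system is
#' reduced to its (symmetric positive definite) pressure Schur
#' complement and solved by conjugate gradients, with the three
#' per-component viscous blocks factored once by sparse Cholesky.
#' The solution is linear in the applied pressure drop by construction.
#'
#' Fluid cells connected to neither pressure face are excluded (their
#' pressure is undefined and their velocity is identically zero). When
#' no fluid path connects the two pressure faces, a zero-flux field with
#' the `percolating = FALSE` flag is returned.
#'
#' @param problem a [flow_problem()].
#' @param tol relative tolerance of the pressure CG solve; the momentum
#'   and divergence residuals are reported in the result.
#' @param max_iter CG iteration cap.
#' @return A `flow_field`: staggered velocities (`u`, `v`, `w` in um/s,
#'   where `u` is along the flow axis of the permuted frame), cell
#'   pressures (Pa), fluxes (um^3/s), diagnostics and metadata.
#' @export
solve_stokes <- function(problem, tol = 1e-8, max_iter = 5000) {
  stopifnot(inherits(problem, "flow_problem"))
  h <- problem$geometry$voxel_size_um
  mu <- problem$viscosity
  dp <- problem$pressure_drop
  pm <- flow_perm(problem$direction)
  lab <- aperm(problem$geometry$data, pm$fwd)
  fluid <- lab == 0L
  d <- dim(fluid)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  if (!any(fluid)) stop("fluid (pore) phase is empty")
  comp <- array(label_components_cpp(as.vector(fluid), d, 6L), dim = d)
  inlet_comps <- setdiff(unique(as.vector(comp[, , 1])), 0L)
  outlet_comps <- setdiff(unique(as.vector(comp[, , nx])), 0L)
  percolating <- length(intersect(inlet_comps, outlet_comps)) > 0
  keep <- union(inlet_comps, outlet_comps)
  fl <- fluid & array(comp %in% keep, dim = d)
  zero_field <- function() {
    structure(list(
      u = array(0, c(nz, ny, nx + 1)), v = array(0, c(nz, ny + 1, nx)),
      w = array(0, c(nz + 1, ny, nx)),
      p = array(NA_real_, d), fluid = fluid, kept = fl,
      Q_in = 0, Q_out = 0, percolating = FALSE, converged = TRUE,
      div_rel_max = 0, cg_iterations = 0L,
      voxel_size_um = h, problem = problem, perm = pm), class = "flow_field")
  }
  if (!percolating) return(zero_field())

  # --- face activity -------------------------------------------------
  uact <- array(FALSE, c(nz, ny, nx + 1))
  uact[, , 2:nx] <- fl[, , 1:(nx - 1)] & fl[, , 2:nx]
  uact[, , 1] <- fl[, , 1]
  uact[, , nx + 1] <- fl[, , nx]
  vact <- array(FALSE, c(nz, ny + 1, nx))
  if (ny > 1) vact[, 2:ny, ] <- fl[, 1:(ny - 1), ] & fl[, 2:ny, ]
  wact <- array(FALSE, c(nz + 1, ny, nx))
  if (nz > 1) wact[2:nz, , ] <- fl[1:(nz - 1), , ] & fl[2:nz, , ]
  # "any fluid flank" marks real faces (u = 0 Dirichlet) vs solid walls
  uany <- array(FALSE, c(nz, ny, nx + 1))
  uany[, , 1:nx] <- fl
  uany[, , 2:(nx + 1)] <- uany[, , 2:(nx + 1)] | fl
  vany <- array(FALSE, c(nz, ny + 1, nx))
  vany[, 1:ny, ] <- fl
  vany[, 2:(ny + 1), ] <- vany[, 2:(ny + 1), ] | fl
  wany <- array(FALSE, c(nz + 1, ny, nx))
  wany[1:nz, , ] <- fl
  wany[2:(nz + 1), , ] <- wany[2:(nz + 1), , ] | fl

  pid <- array(0L, d)
  pid[fl] <- seq_len(sum(fl))
  ncell <- sum(fl)

  assemble <- function(act, anyf, axis, grid_dim, omega) {
    # axis: which of (z,y,x) in the permuted frame is this component's
    # normal; builds the SPD viscous block, returning triplets + diag
    fid <- array(0L, grid_dim)
    fid[act] <- seq_len(sum(act))
    nf <- sum(act)
    ii <- integer(0); jj <- integer(0); xx <- numeric(0)
    diag_acc <- numeric(nf)
    co <- which(act, arr.ind = TRUE)
    om <- omega(co)
    for (dir_axis in 1:3) {
      for (sgn in c(-1L, 1L)) {
        nb <- co
        nb[, dir_axis] <- nb[, dir_axis] + sgn
        inb <- nb[, dir_axis] >= 1 & nb[, dir_axis] <= grid_dim[dir_axis]
        kap <- mu * h * (if (dir_axis == axis) rep(1, length(om)) else om)
        # in-bounds neighbours
        idx_in <- which(inb)
        if (length(idx_in)) {
          nb_lin <- (nb[idx_in, 3] - 1) * (grid_dim[1] * grid_dim[2]) +
            (nb[idx_in, 2] - 1) * grid_dim[1] + nb[idx_in, 1]
          nb_id <- fid[nb_lin]
          act_nb <- nb_id > 0
          # active neighbour: off-diagonal coupling
          a <- idx_in[act_nb]
          if (length(a)) {
            ii <- c(ii, a)
            jj <- c(jj, nb_id[act_nb])
            xx <- c(xx, -kap[a])
            diag_acc[a] <- diag_acc[a] + kap[a]
          }
          # inactive neighbour: Dirichlet-0 face or solid wall
          b <- idx_in[!act_nb]
          if (length(b)) {
            anyf_nb <- anyf[nb_lin[!act_nb]]
            if (dir_axis == axis) {
              diag_acc[b] <- diag_acc[b] + kap[b]   # face with u = 0
            } else {
              wall <- !anyf_nb                       # full solid row
              diag_acc[b[wall]] <- diag_acc[b[wall]] + 2 * kap[b[wall]]
              diag_acc[b[!wall]] <- diag_acc[b[!wall]] + kap[b[!wall]]
            }
          }
        }
        # out-of-bounds neighbours
        idx_out <- which(!inb)
        if (length(idx_out)) {
          if (dir_axis == axis && axis == 3) {
            # beyond inlet/outlet along the flow axis: zero gradient
          } else if (dir_axis == 3 && axis != 3) {
            # tangential at the pressure faces: zero gradient
          } else if (dir_axis == axis) {
            # normal component at its own lateral wall cannot happen
            # (boundary faces of v/w are inactive)
          } else {
            if (problem$lateral == "noslip") {
              diag_acc[idx_out] <- diag_acc[idx_out] + 2 * kap[idx_out]
            } # slip: zero contribution
          }
        }
      }
    }
    list(fid = fid, nf = nf, ii = ii, jj = jj, xx = xx, diag = diag_acc,
         co = co)
  }

  omega_u <- function(co) ifelse(co[, 3] == 1 | co[, 3] == nx + 1, 0.5, 1)
  omega_1 <- function(co) rep(1, nrow(co))

  au <- assemble(uact, uany, 3L, c(nz, ny, nx + 1), omega_u)
  av <- assemble(vact, vany, 2L, c(nz, ny + 1, nx), omega_1)
  aw <- assemble(wact, wany, 1L, c(nz + 1, ny, nx), omega_1)

  build_A <- function(a) {
    A <- Matrix::sparseMatrix(i = c(a$ii, seq_len(a$nf)),
                              j = c(a$jj, seq_len(a$nf)),
                              x = c(a$xx, a$diag),
                              dims = c(a$nf, a$nf))
    methods::as(Matrix::forceSymmetric(A), "CsparseMatrix")
  }

  # gradient operators (face x cell) and boundary RHS, vectorized
  h2 <- h * h
  cell_lin <- function(z, y, x) z + nz * ((y - 1) + ny * (x - 1))
  co_u <- au$co
  zu <- co_u[, 1]; yu <- co_u[, 2]; iu <- co_u[, 3]
  hasL <- iu >= 2
  hasR <- iu <= nx
  gu_i <- c(which(hasL), which(hasR))
  gu_j <- c(pid[cell_lin(zu[hasL], yu[hasL], iu[hasL] - 1)],
            pid[cell_lin(zu[hasR], yu[hasR], iu[hasR])])
  gu_x <- c(rep(-h2, sum(hasL)), rep(h2, sum(hasR)))
  bu <- numeric(au$nf)
  bu[!hasL] <- h2 * dp           # p_in on the inlet boundary faces
  Gv_triplets <- function(a, axis) {
    co <- a$co
    z <- co[, 1]; y <- co[, 2]; x <- co[, 3]
    if (axis == 2L) {
      jlo <- pid[cell_lin(z, y - 1, x)]
    } else {
      jlo <- pid[cell_lin(z - 1, y, x)]
    }
    jhi <- pid[cell_lin(z, y, x)]
    list(i = c(seq_len(a$nf), seq_len(a$nf)), j = c(jlo, jhi),
         x = c(rep(-h2, a$nf), rep(h2, a$nf)))
  }
  gv <- if (av$nf) Gv_triplets(av, 2L) else list(i = integer(0), j = integer(0), x = numeric(0))
  gw <- if (aw$nf) Gv_triplets(aw, 1L) else list(i = integer(0), j = integer(0), x = numeric(0))

  Gu <- Matrix::sparseMatrix(i = gu_i, j = gu_j, x = gu_x,
                             dims = c(au$nf, ncell))
  Gv <- Matrix::sparseMatrix(i = gv$i, j = gv$j, x = gv$x,
                             dims = c(av$nf, ncell))
  Gw <- Matrix::sparseMatrix(i = gw$i, j = gw$j, x = gw$x,
                             dims = c(aw$nf, ncell))

  Au <- build_A(au); Av <- build_A(av); Aw <- build_A(aw)
  ch <- tryCatch(
    list(u = Matrix::Cholesky(Au, LDL = FALSE),
         v = if (av$nf) Matrix::Cholesky(Av, LDL = FALSE) else NULL,
         w = if (aw$nf) Matrix::Cholesky(Aw, LDL = FALSE) else NULL),
    error = function(e) {
      stop("viscous block not positive definite (an obstacle-free domain ",
           "with free-slip lateral walls has no steady solution; use ",
           "lateral = \"noslip\"): ", conditionMessage(e))
    })
  solve_blk <- function(chol_f, rhs) {
    if (is.null(chol_f)) return(rhs * 0)
    as.numeric(Matrix::solve(chol_f, rhs, system = "A"))
  }
  S_apply <- function(p) {
    r <- as.numeric(Matrix::crossprod(Gu, solve_blk(ch$u, Gu %*% p)))
    if (av$nf) r <- r + as.numeric(Matrix::crossprod(Gv, solve_blk(ch$v, Gv %*% p)))
    if (aw$nf) r <- r + as.numeric(Matrix::crossprod(Gw, solve_blk(ch$w, Gw %*% p)))
    r
  }
  rhs_p <- as.numeric(Matrix::crossprod(Gu, solve_blk(ch$u, bu)))
  # conjugate gradients on the SPD Schur complement
  p <- numeric(ncell)
  r <- rhs_p
  dvec <- r
  rs <- sum(r * r)
  rhs_norm <- sqrt(sum(rhs_p^2))
  it <- 0L
  converged <- rhs_norm == 0
  while (!converged && it < max_iter) {
    q <- S_apply(dvec)
    alpha <- rs / sum(dvec * q)
    p <- p + alpha * dvec
    r <- r - alpha * q
    rs_new <- sum(r * r)
    it <- it + 1L
    if (sqrt(rs_new) <= tol * rhs_norm) {
      converged <- TRUE
      break
    }
    dvec <- r + (rs_new / rs) * dvec
    rs <- rs_new
  }
  if (!converged) {
    stop(sprintf(paste0("Stokes pressure solve did not converge in %d ",
                        "iterations (relative residual %.3g)"),
                 max_iter, sqrt(rs) / rhs_norm))
  }
  uvec <- solve_blk(ch$u, bu - as.numeric(Gu %*% p))
  vvec <- if (av$nf) solve_blk(ch$v, -as.numeric(Gv %*% p)) else numeric(0)
  wvec <- if (aw$nf) solve_blk(ch$w, -as.numeric(Gw %*% p)) else numeric(0)

  U <- array(0, c(nz, ny, nx + 1)); U[uact] <- uvec
  V <- array(0, c(nz, ny + 1, nx)); if (av$nf) V[vact] <- vvec
  W <- array(0, c(nz + 1, ny, nx)); if (aw$nf) W[wact] <- wvec
  P <- array(NA_real_, d)
  P[fl] <- p

  div <- (U[, , 2:(nx + 1), drop = FALSE] - U[, , 1:nx, drop = FALSE]) +
    (V[, 2:(ny + 1), , drop = FALSE] - V[, 1:ny, , drop = FALSE]) +
    (W[2:(nz + 1), , , drop = FALSE] - W[1:nz, , , drop = FALSE])
  umax <- max(abs(U), abs(V), abs(W), 1e-300)
  div_rel <- max(abs(div[fl])) / umax
  Q_in <- h2 * sum(U[, , 1])
  Q_out <- h2 * sum(U[, , nx + 1])
  structure(list(u = U, v = V, w = W, p = P, fluid = fluid, kept = fl,
                 Q_in = Q_in, Q_out = Q_out, percolating = TRUE,
                 converged = TRUE, div_rel_max = div_rel,
                 cg_iterations = it, voxel_size_um = h,
                 problem = problem, perm = pm),
            class = "flow_field")
}

#' @export
print.flow_field <- function(x, ...) {
  cat(sprintf("<flow_field> dir %s, dp %.3g Pa, %s\n",
              x$problem$direction, x$problem$pressure_drop,
              if (x$percolating) "percolating" else "non-percolating"))
  cat(sprintf("  Q_in %.4g um^3/s, Q_out %.4g um^3/s, max rel divergence %.2g\n",
              x$Q_in, x$Q_out, x$div_rel_max))
  invisible(x)
}

#' Darcy permeability from a solved flow field
#'
#' `k = Q mu L / (A dp)` with `L` the domain length along the flow
#' direction and `A` the full cross-sectional area (solid included), so
#' `k` is the empirical permeability of the composite medium in um^2.
#'
#' @param field a `flow_field` from [solve_stokes()].
#' @return Permeability in um^2 (0 for a non-percolating geometry).
#' @export
permeability <- function(field) {
  stopifnot(inherits(field, "flow_field"))
  if (!field$percolating) return(0)
  d <- dim(field$fluid)
  h <- field$voxel_size_um
  L <- d[3] * h
  A <- d[1] * d[2] * h^2
  Q <- (field$Q_in + field$Q_out) / 2
  Q * field$problem$viscosity * L / (A * field$problem$pressure_drop)
}

# cell-centered speed over kept fluid cells
cell_speeds <- function(field) {
  d <- dim(field$fluid)
  nz <- d[1]; ny <- d[2]; nx <- d[3]
  uc <- (field$u[, , 1:nx, drop = FALSE] +
           field$u[, , 2:(nx + 1), drop = FALSE]) / 2
  vc <- (field$v[, 1:ny, , drop = FALSE] +
           field$v[, 2:(ny + 1), , drop = FALSE]) / 2
  wc <- (field$w[1:nz, , , drop = FALSE] +
           field$w[2:(nz + 1), , , drop = FALSE]) / 2
  sp <- sqrt(uc^2 + vc^2 + wc^2)
  sp[field$kept]
}

#' Distribution of flow speeds over fluid cells
#'
#' @param field a converged `flow_field`.
#' @param n_bins histogram bin count.
#' @return A tibble histogram (bin midpoints in um/s, counts, normalized
#'   frequency and its log10) with attributes `mean_speed` and
#'   `max_speed`.
#' @export
velocity_distribution <- function(field, n_bins = 50) {
  sp <- cell_speeds(field)
  brk <- seq(0, max(sp) * (1 + 1e-9) + 1e-300, length.out = n_bins + 1)
  hh <- graphics::hist(sp, breaks = brk, plot = FALSE)
  out <- tibble::tibble(speed_um_s = hh$mids, count = hh$counts,
                        frequency = hh$counts / sum(hh$counts))
  out$log10_frequency <- ifelse(out$frequency > 0, log10(out$frequency),
                                NA_real_)
  attr(out, "mean_speed") <- mean(sp)
  attr(out, "max_speed") <- max(sp)
  out
}

# trilinear interpolation of the staggered field at point pt = (z,y,x)
# in cell-center voxel coordinates (cells at 0..n-1)
interp_velocity <- function(field, pt) {
  comp <- function(arr, oz, oy, ox) {
    dz <- dim(arr)
    iz <- min(max(pt[1] + oz, 1), dz[1])
    iy <- min(max(pt[2] + oy, 1), dz[2])
    ix <- min(max(pt[3] + ox, 1), dz[3])
    z0 <- floor(iz); y0 <- floor(iy); x0 <- floor(ix)
    z1 <- min(z0 + 1, dz[1]); y1 <- min(y0 + 1, dz[2]); x1 <- min(x0 + 1, dz[3])
    fz <- iz - z0; fy <- iy - y0; fx <- ix - x0
    c00 <- arr[z0, y0, x0] * (1 - fz) + arr[z1, y0, x0] * fz
    c10 <- arr[z0, y1, x0] * (1 - fz) + arr[z1, y1, x0] * fz
    c01 <- arr[z0, y0, x1] * (1 - fz) + arr[z1, y0, x1] * fz
    c11 <- arr[z0, y1, x1] * (1 - fz) + arr[z1, y1, x1] * fz
    (c00 * (1 - fy) + c10 * fy) * (1 - fx) + (c01 * (1 - fy) + c11 * fy) * fx
  }
  c(w = comp(field$w, 1.5, 1, 1),
    v = comp(field$v, 1, 1.5, 1),
    u = comp(field$u, 1, 1, 1.5))
}

#' Streamline flow tortuosity
#'
#' Streamlines are integrated through the velocity field with 4th-order
#' Runge-Kutta steps and trilinear interpolation, seeded on inlet-face
#' fluid cells with probability proportional to the local influx (so
#' fast channels are represented in proportion to the flow they carry).
#' Tortuosity is the streamline arc length over the straight distance
#' between its endpoints; streamlines shorter than `min_length_um` are
#' discarded, mirroring the protocol of ignoring paths shorter than a
#' pore (within one pore flow is effectively straight).
#'
#' @param field a converged, percolating `flow_field`.
#' @param min_length_um minimal accepted arc length (default 85 um).
#' @param n_streamlines number of seeds.
#' @param seed integer seed for the seed draw.
#' @param step_vox integration step, voxels.
#' @return Tibble (streamline, arc_um, chord_um, tortuosity) with
#'   attribute `median_tortuosity`.
#' @export
flow_tortuosity <- function(field, min_length_um = 85, n_streamlines = 100,
                            seed = 1, step_vox = 0.25) {
  stopifnot(inherits(field, "flow_field"))
  if (!field$percolating) stop("field is non-percolating")
  d <- dim(field$fluid)
  h <- field$voxel_size_um
  influx <- field$u[, , 1]
  influx[!field$kept[, , 1]] <- 0
  influx[influx < 0] <- 0
  if (sum(influx) <= 0) stop("no inflow on the inlet face")
  cells <- which(influx > 0)
  wts <- influx[cells] / sum(influx[cells])
  picks <- with_seed(seed, sample(length(cells), n_streamlines,
                                  replace = TRUE, prob = wts))
  zy <- arrayInd(cells[picks], dim(influx))
  vmax <- max(abs(field$u), abs(field$v), abs(field$w))
  max_steps <- ceiling(20 * sum(d) / step_vox)
  res <- vector("list", n_streamlines)
  for (s in seq_len(n_streamlines)) {
    pt <- c(zy[s, 1] - 1, zy[s, 2] - 1, -0.45)
    start <- pt
    arc <- 0
    steps <- 0
    repeat {
      k1 <- interp_velocity(field, pt)
      sp1 <- sqrt(sum(k1^2))
      if (sp1 < 1e-12 * vmax) break
      f1 <- k1 / sp1
      k2 <- interp_velocity(field, pt + 0.5 * step_vox * f1)
      f2 <- k2 / max(sqrt(sum(k2^2)), 1e-300)
      k3 <- interp_velocity(field, pt + 0.5 * step_vox * f2)
      f3 <- k3 / max(sqrt(sum(k3^2)), 1e-300)
      k4 <- interp_velocity(field, pt + step_vox * f3)
      f4 <- k4 / max(sqrt(sum(k4^2)), 1e-300)
      move <- step_vox * (f1 + 2 * f2 + 2 * f3 + f4) / 6
      pt <- pt + move
      arc <- arc + sqrt(sum(move^2))
      steps <- steps + 1
      if (any(pt < -0.5) || any(pt > d - 0.5) || steps >= max_steps) break
    }
    chord <- sqrt(sum((pt - start)^2))
    res[[s]] <- c(arc = arc * h, chord = chord * h)
  }
  tb <- tibble::tibble(
    streamline = seq_len(n_streamlines),
    arc_um = vapply(res, `[[`, numeric(1), "arc"),
    chord_um = vapply(res, `[[`, numeric(1), "chord"))
  tb$tortuosity <- tb$arc_um / pmax(tb$chord_um, 1e-300)
  tb <- tb[tb$arc_um >= min_length_um, ]
  if (!nrow(tb)) {
    stop("all streamlines are shorter than min_length_um = ", min_length_um,
         " um; choose a smaller minimal length")
  }
  attr(tb, "median_tortuosity") <- stats::median(tb$tortuosity)
  tb
}
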