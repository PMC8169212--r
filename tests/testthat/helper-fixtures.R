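# Shared fixture builders and independent oracles used across test files.

# voxelized sphere mask (center in 0-based voxel coordinates)
sphere_mask <- function(dims, center, radius) {
  co <- arrayInd(seq_len(prod(dims)), dims) - 1
  array(sqrt(rowSums(sweep(co, 2, center)^2)) <= radius, dims)
}

# tube rasterized by sweeping a ball along a polyline (voxel coords)
tube_mask <- function(dims, pts, radius, step = 0.35) {
  seglen <- sqrt(rowSums(diff(pts)^2))
  s <- c(0, cumsum(seglen))
  ss <- seq(0, s[length(s)], by = step)
  fine <- sapply(1:3, function(k) approx(s, pts[, k], xout = ss)$y)
  res <- mesotissue:::stamp_balls_cpp(dims, fine, rep(radius, nrow(fine)))
  array(res$mask, dims)
}

# random abstract pore network for percolation tests
random_network <- function(np, seed) {
  set.seed(seed)
  pores <- tibble::tibble(pore = 1:np,
                          diameter_um = runif(np, 5, 50),
                          touches_boundary = runif(np) < 0.2)
  if (!any(pores$touches_boundary)) pores$touches_boundary[1] <- TRUE
  ne <- sample(np:(3 * np), 1)
  a <- sample(np, ne, replace = TRUE)
  b <- sample(np, ne, replace = TRUE)
  keep <- a != b
  th <- tibble::tibble(pore_a = pmin(a, b)[keep], pore_b = pmax(a, b)[keep],
                       diameter_um = runif(sum(keep), 2, 40))
  th <- th[!duplicated(paste(th$pore_a, th$pore_b)), ]
  pore_network(pores, th)
}

# exhaustive threshold-sweep BFS oracle for the critical diameter
bfs_critical_diameter <- function(net, src) {
  diams <- sort(unique(c(net$pores$diameter_um, net$throats$diameter_um)),
                decreasing = TRUE)
  np <- max(net$pores$pore)
  for (t in diams) {
    pok <- rep(FALSE, np)
    pok[net$pores$pore] <- net$pores$diameter_um >= t
    tok <- net$throats$diameter_um >= t & pok[net$throats$pore_a] &
      pok[net$throats$pore_b]
    adj <- vector("list", np)
    for (i in which(tok)) {
      a <- net$throats$pore_a[i]
      b <- net$throats$pore_b[i]
      adj[[a]] <- c(adj[[a]], b)
      adj[[b]] <- c(adj[[b]], a)
    }
    if (!pok[src]) next
    seen <- logical(np)
    seen[src] <- TRUE
    q <- src
    while (length(q)) {
      v <- q[1]
      q <- q[-1]
      for (wv in adj[[v]]) {
        if (!seen[wv]) {
          seen[wv] <- TRUE
          q <- c(q, wv)
        }
      }
    }
    bp <- net$pores$pore[net$pores$touches_boundary &
                           net$pores$diameter_um >= t]
    if (any(seen[bp])) return(t)
  }
  0
}

# independent 12-pass fusion reference: explicit per-slice loops and
# explicit coordinate rotations, no shared code with the package
naive_multi_view <- function(arr, predictor) {
  stopifnot(dim(arr)[2] == dim(arr)[3])
  rot1 <- function(a) {
    # 90 deg CCW about z, one slice at a time
    d <- dim(a)
    out <- array(0, c(d[1], d[3], d[2]))
    for (k in seq_len(d[1])) {
      m <- a[k, , ]
      out[k, , ] <- t(m)[ncol(m):1, ]
    }
    out
  }
  votes <- array(0L, dim(arr))
  for (k in 0:3) {
    rot <- arr
    if (k > 0) for (i in 1:k) rot <- rot1(rot)
    for (plane in c("xy", "xz", "yz")) {
      d <- dim(rot)
      mask <- array(0L, d)
      if (plane == "xy") {
        for (s in seq_len(d[1])) mask[s, , ] <- predictor(rot[s, , ])
      } else if (plane == "xz") {
        for (s in seq_len(d[2])) mask[, s, ] <- predictor(rot[, s, ])
      } else {
        for (s in seq_len(d[3])) mask[, , s] <- predictor(rot[, , s])
      }
      back <- mask
      if (k > 0) for (i in 1:(4 - k)) back <- rot1(back)
      votes <- votes + back
    }
  }
  votes
}

# Monte-Carlo two-point probability at a set of integer lag vectors
pair_sampling_s2 <- function(mask, lags, n_pairs, seed) {
  set.seed(seed)
  d <- dim(mask)
  out <- numeric(nrow(lags))
  for (i in seq_len(nrow(lags))) {
    lg <- lags[i, ]
    lo <- pmax(1, 1 - lg)
    hi <- pmin(d, d - lg)
    z <- sample(lo[1]:hi[1], n_pairs, replace = TRUE)
    y <- sample(lo[2]:hi[2], n_pairs, replace = TRUE)
    x <- sample(lo[3]:hi[3], n_pairs, replace = TRUE)
    out[i] <- mean(mask[cbind(z, y, x)] &
                     mask[cbind(z + lg[1], y + lg[2], x + lg[3])])
  }
  out
}
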