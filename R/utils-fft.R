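# FFT helpers shared by the grayscale renderer, the pore separator and the
# autocorrelation estimator.

# smallest 5-smooth integer >= n (keeps R's mixed-radix FFT fast)
next_fast_len <- function(n) {
  k <- as.integer(ceiling(n))
  repeat {
    m <- k
    for (p in c(2L, 3L, 5L)) while (m %% p == 0L) m <- m %/% p
    if (m == 1L) return(k)
    k <- k + 1L
  }
}

# frequency-sample Gaussian along one axis of length n (period n), sd in voxels
gauss_kernel_1d <- function(n, sigma) {
  x <- c(0:(n %/% 2), -((n - n %/% 2 - 1):1))
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian blur of a 3D array via padded FFT (edge replication
# is not used; the array is zero-padded by 4 sigma and renormalized by the
# blurred support indicator so that borders are not darkened)
gaussian_blur3 <- function(arr, sigma) {
  if (sigma <= 0) return(arr)
  d <- dim(arr)
  pad <- ceiling(4 * sigma)
  pd <- vapply(d + 2 * pad, next_fast_len, integer(1))
  big <- array(0, dim = pd)
  sup <- array(0, dim = pd)
  idx <- lapply(1:3, function(ax) pad + seq_len(d[ax]))
  big[idx[[1]], idx[[2]], idx[[3]]] <- arr
  sup[idx[[1]], idx[[2]], idx[[3]]] <- 1
  K <- outer(outer(fft(gauss_kernel_1d(pd[1], sigma)),
                   fft(gauss_kernel_1d(pd[2], sigma))),
             fft(gauss_kernel_1d(pd[3], sigma)))
  dim(K) <- pd
  bl <- Re(fft(fft(big) * K, inverse = TRUE)) / prod(pd)
  sp <- Re(fft(fft(sup) * K, inverse = TRUE)) / prod(pd)
  out <- bl[idx[[1]], idx[[2]], idx[[3]]] /
    pmax(sp[idx[[1]], idx[[2]], idx[[3]]], 1e-12)
  dim(out) <- d
  out
}

# 3D summed-area table: S[i,j,k] = sum of arr[1:i,1:j,1:k]
integral_image3 <- function(arr) {
  s <- apply(arr, c(2, 3), cumsum)
  s <- apply(s, c(1, 3), cumsum)   # now dim (y, z, x)
  s <- apply(s, c(2, 1), cumsum)   # cumsum over x -> dim (x, z, y)
  aperm(s, c(2, 3, 1))
}

# block sum over a half-open box (0-based origin o, extent e) from the table
box_sum <- function(S, o, e) {
  g <- function(i, j, k) {
    if (i < 1 || j < 1 || k < 1) return(0)
    S[i, j, k]
  }
  z0 <- o[1]; y0 <- o[2]; x0 <- o[3]
  z1 <- o[1] + e[1]; y1 <- o[2] + e[2]; x1 <- o[3] + e[3]
  g(z1, y1, x1) - g(z0, y1, x1) - g(z1, y0, x1) - g(z1, y1, x0) +
    g(z0, y0, x1) + g(z0, y1, x0) + g(z1, y0, x0) - g(z0, y0, x0)
}
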