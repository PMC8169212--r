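#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 1D squared-distance transform (lower envelope of parabolas),
// Felzenszwalb & Huttenlocher style. f: input costs, d: output.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -1e30;
  z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance transform of a 3D foreground mask:
// distance from each foreground voxel to the nearest background voxel
// center, in voxel units. Array layout is (z, y, x) column-major.
// [[Rcpp::export]]
NumericVector edt3d_sq_cpp(LogicalVector fg, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t N = (R_xlen_t)nz * ny * nx;
  NumericVector g(N);
  const double INF = 1e20;
  for (R_xlen_t i = 0; i < N; ++i) g[i] = fg[i] ? INF : 0.0;

  int nmax = std::max(nz, std::max(ny, nx));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along z (stride 1)
  for (int x = 0; x < nx; ++x)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
      for (int i = 0; i < nz; ++i) f[i] = g[base + i];
      dt1d(f, d, v, z, nz);
      for (int i = 0; i < nz; ++i) g[base + i] = d[i];
    }
  // pass along y (stride nz)
  for (int x = 0; x < nx; ++x)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * ny * x;
      for (int i = 0; i < ny; ++i) f[i] = g[base + (R_xlen_t)nz * i];
      dt1d(f, d, v, z, ny);
      for (int i = 0; i < ny; ++i) g[base + (R_xlen_t)nz * i] = d[i];
    }
  // pass along x (stride nz*ny)
  const R_xlen_t sx = (R_xlen_t)nz * ny;
  for (int y = 0; y < ny; ++y)
    for (int zz = 0; zz < nz; ++zz) {
      R_xlen_t base = zz + (R_xlen_t)nz * y;
      for (int i = 0; i < nx; ++i) f[i] = g[base + sx * i];
      dt1d(f, d, v, z, nx);
      for (int i = 0; i < nx; ++i) g[base + sx * i] = d[i];
    }
  return g;
}
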