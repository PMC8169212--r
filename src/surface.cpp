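#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Triangulated area of the `iso` level surface of a scalar field sampled
// at voxel centers. Each 2x2x2 cell is split into the six Kuhn tetrahedra
// around its main diagonal (a tetrahedral variant of marching cubes with
// linear interpolation along edges); the decomposition is identical in
// every cell, so triangles match across shared faces. Domain boundary
// faces are never capped. Positions are in voxel units; multiply the
// result by voxel_size^2 for physical area.

static inline double tri_area(const double a[3], const double b[3],
                              const double c[3]) {
  double u[3] = {b[0] - a[0], b[1] - a[1], b[2] - a[2]};
  double v[3] = {c[0] - a[0], c[1] - a[1], c[2] - a[2]};
  double w[3] = {u[1] * v[2] - u[2] * v[1],
                 u[2] * v[0] - u[0] * v[2],
                 u[0] * v[1] - u[1] * v[0]};
  return 0.5 * std::sqrt(w[0] * w[0] + w[1] * w[1] + w[2] * w[2]);
}

static inline void interp(const double p1[3], const double p2[3],
                          double v1, double v2, double iso, double out[3]) {
  double t = (iso - v1) / (v2 - v1);
  for (int k = 0; k < 3; ++k) out[k] = p1[k] + t * (p2[k] - p1[k]);
}

// corners of a unit cell in (z,y,x) offsets; the 6 Kuhn tetrahedra
// traverse 000 -> e1 -> e1+e2 -> 111 for each axis permutation
static const int CORNER[8][3] = {
  {0,0,0},{1,0,0},{0,1,0},{1,1,0},{0,0,1},{1,0,1},{0,1,1},{1,1,1}
};
static inline int corner_id(int dz, int dy, int dx) { return dz + 2 * dy + 4 * dx; }

// [[Rcpp::export]]
double iso_area_cpp(NumericVector field, IntegerVector dim, double iso) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  // precompute tetrahedra corner ids from axis permutations
  int tets[6][4];
  int perms[6][3] = {{0,1,2},{0,2,1},{1,0,2},{1,2,0},{2,0,1},{2,1,0}};
  for (int t = 0; t < 6; ++t) {
    int e[3][3] = {{0,0,0},{0,0,0},{0,0,0}};
    e[0][perms[t][0]] = 1;
    e[1][perms[t][0]] = 1; e[1][perms[t][1]] = 1;
    e[2][0] = e[2][1] = e[2][2] = 1;
    tets[t][0] = corner_id(0, 0, 0);
    tets[t][1] = corner_id(e[0][0], e[0][1], e[0][2]);
    tets[t][2] = corner_id(e[1][0], e[1][1], e[1][2]);
    tets[t][3] = corner_id(e[2][0], e[2][1], e[2][2]);
  }
  double total = 0.0;
  double vals[8];
  double pos[8][3];
  for (int x = 0; x < nx - 1; ++x)
    for (int y = 0; y < ny - 1; ++y)
      for (int z = 0; z < nz - 1; ++z) {
        bool any_lo = false, any_hi = false;
        for (int c = 0; c < 8; ++c) {
          int zz = z + CORNER[c][0], yy = y + CORNER[c][1], xx = x + CORNER[c][2];
          double v = field[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
          vals[c] = v;
          pos[c][0] = zz; pos[c][1] = yy; pos[c][2] = xx;
          if (v > iso) any_hi = true; else any_lo = true;
        }
        if (!any_lo || !any_hi) continue;
        for (int t = 0; t < 6; ++t) {
          int id[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int above[4], nab = 0, nbel = 0;
          int ia[4], ib[4];
          for (int k = 0; k < 4; ++k) {
            above[k] = vals[id[k]] > iso;
            if (above[k]) ia[nab++] = id[k]; else ib[nbel++] = id[k];
          }
          if (nab == 0 || nab == 4) continue;
          double q[4][3];
          if (nab == 1 || nab == 3) {
            int a = (nab == 1) ? ia[0] : ib[0];
            int others[3]; int m = 0;
            for (int k = 0; k < 4; ++k)
              if (id[k] != a) others[m++] = id[k];
            for (int k = 0; k < 3; ++k)
              interp(pos[a], pos[others[k]], vals[a], vals[others[k]], iso, q[k]);
            total += tri_area(q[0], q[1], q[2]);
          } else { // 2 above, 2 below: quad a0-b0, a0-b1, a1-b1, a1-b0
            interp(pos[ia[0]], pos[ib[0]], vals[ia[0]], vals[ib[0]], iso, q[0]);
            interp(pos[ia[0]], pos[ib[1]], vals[ia[0]], vals[ib[1]], iso, q[1]);
            interp(pos[ia[1]], pos[ib[1]], vals[ia[1]], vals[ib[1]], iso, q[2]);
            interp(pos[ia[1]], pos[ib[0]], vals[ia[1]], vals[ib[0]], iso, q[3]);
            total += tri_area(q[0], q[1], q[2]) + tri_area(q[0], q[2], q[3]);
          }
        }
      }
  return total;
}
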