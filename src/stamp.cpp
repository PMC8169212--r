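#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Rasterize a union of balls with the center-inclusion rule: a voxel
// belongs to a ball iff its center lies within the radius. Centers are
// continuous (z, y, x) coordinates in voxel units, 0-based. Returns the
// union mask and the cumulative number of covered voxels after each ball
// (monotone, used to bisect a target volume fraction).
// [[Rcpp::export]]
List stamp_balls_cpp(IntegerVector dim, NumericMatrix centers,
                     NumericVector radii) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t N = (R_xlen_t)nz * ny * nx;
  LogicalVector mask(N);
  const int nb = centers.nrow();
  NumericVector cum(nb);
  double covered = 0;
  for (int b = 0; b < nb; ++b) {
    const double cz = centers(b, 0), cy = centers(b, 1), cx = centers(b, 2);
    const double r = radii[b], r2 = r * r;
    const int z0 = std::max(0, (int)std::ceil(cz - r));
    const int z1 = std::min(nz - 1, (int)std::floor(cz + r));
    const int y0 = std::max(0, (int)std::ceil(cy - r));
    const int y1 = std::min(ny - 1, (int)std::floor(cy + r));
    const int x0 = std::max(0, (int)std::ceil(cx - r));
    const int x1 = std::min(nx - 1, (int)std::floor(cx + r));
    for (int x = x0; x <= x1; ++x) {
      const double dx2 = (x - cx) * (x - cx);
      if (dx2 > r2) continue;
      for (int y = y0; y <= y1; ++y) {
        const double dxy2 = dx2 + (y - cy) * (y - cy);
        if (dxy2 > r2) continue;
        const R_xlen_t base = (R_xlen_t)nz * (y + (R_xlen_t)ny * x);
        for (int z = z0; z <= z1; ++z) {
          if (dxy2 + (z - cz) * (z - cz) <= r2) {
            R_xlen_t i = base + z;
            if (!mask[i]) {
              mask[i] = true;
              covered += 1;
            }
          }
        }
      }
    }
    cum[b] = covered;
  }
  return List::create(_["mask"] = mask, _["cumulative_covered"] = cum);
}
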