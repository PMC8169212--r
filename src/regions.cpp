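#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

// Marker-controlled watershed by priority flooding: voxels inside `mask`
// are assigned the label of the marker basin that reaches them first,
// processing in ascending order of `elev` (pass the negated distance
// transform to flood from its maxima). FIFO order breaks exact ties.
// [[Rcpp::export]]
IntegerVector watershed_cpp(NumericVector elev, IntegerVector markers,
                            LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t N = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(N);
  typedef std::pair<double, std::pair<long long, R_xlen_t> > Item;
  std::priority_queue<Item, std::vector<Item>, std::greater<Item> > pq;
  long long counter = 0;
  for (R_xlen_t i = 0; i < N; ++i) {
    lab[i] = 0;
    if (markers[i] > 0 && mask[i]) {
      lab[i] = markers[i];
      pq.push(Item(elev[i], std::make_pair(counter++, i)));
    }
  }
  static const int D6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  while (!pq.empty()) {
    R_xlen_t i = pq.top().second.second;
    pq.pop();
    int x = (int)(i / ((R_xlen_t)nz * ny));
    int rem = (int)(i - (R_xlen_t)nz * ny * x);
    int y = rem / nz, z = rem % nz;
    for (int d = 0; d < 6; ++d) {
      int zz = z + D6[d][0], yy = y + D6[d][1], xx = x + D6[d][2];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (!mask[j] || lab[j] != 0) continue;
      lab[j] = lab[i];
      pq.push(Item(elev[j], std::make_pair(counter++, j)));
    }
  }
  return lab;
}

// Connected-component labelling of a mask (6- or 26-connectivity).
// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t N = (R_xlen_t)nz * ny * nx;
  IntegerVector lab(N);
  for (R_xlen_t i = 0; i < N; ++i) lab[i] = 0;
  std::vector<R_xlen_t> stack;
  int cur = 0;
  for (R_xlen_t s = 0; s < N; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++cur;
    lab[s] = cur;
    stack.push_back(s);
    while (!stack.empty()) {
      R_xlen_t i = stack.back();
      stack.pop_back();
      int x = (int)(i / ((R_xlen_t)nz * ny));
      int rem = (int)(i - (R_xlen_t)nz * ny * x);
      int y = rem / nz, z = rem % nz;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dz == 0 && dy == 0 && dx == 0) continue;
            int nd = std::abs(dz) + std::abs(dy) + std::abs(dx);
            if (connectivity == 6 && nd > 1) continue;
            int zz = z + dz, yy = y + dy, xx = x + dx;
            if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
              continue;
            R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
            if (!mask[j] || lab[j] != 0) continue;
            lab[j] = cur;
            stack.push_back(j);
          }
    }
  }
  return lab;
}

// Indices (1-based) of voxels in `mask` whose value is >= all of their
// 26-neighbours inside the mask (plateau voxels all qualify; the caller
// applies minimum-separation suppression).
// [[Rcpp::export]]
IntegerVector local_maxima_cpp(NumericVector img, LogicalVector mask,
                               IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t N = (R_xlen_t)nz * ny * nx;
  std::vector<R_xlen_t> out;
  for (R_xlen_t i = 0; i < N; ++i) {
    if (!mask[i]) continue;
    int x = (int)(i / ((R_xlen_t)nz * ny));
    int rem = (int)(i - (R_xlen_t)nz * ny * x);
    int y = rem / nz, z = rem % nz;
    bool ok = true;
    for (int dz = -1; dz <= 1 && ok; ++dz)
      for (int dy = -1; dy <= 1 && ok; ++dy)
        for (int dx = -1; dx <= 1 && ok; ++dx) {
          if (dz == 0 && dy == 0 && dx == 0) continue;
          int zz = z + dz, yy = y + dy, xx = x + dx;
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          if (mask[j] && img[j] > img[i]) ok = false;
        }
    if (ok) out.push_back(i + 1);
  }
  return IntegerVector(out.begin(), out.end());
}
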