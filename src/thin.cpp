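#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Topology-preserving 3D thinning to a 1-voxel-wide centerline skeleton.
// A voxel is deletable when it is "simple" in the digital-topology sense
// (Bertrand/Malandain characterization):
//   (a) its foreground 26-neighbours form exactly one 26-connected component,
//   (b) the background voxels of its 18-neighbourhood that are 6-reachable
//       from a face neighbour form exactly one 6-connected component.
// Deletion proceeds in 6 directional sub-iterations (U/D/N/S/E/W border
// voxels), sequentially re-checking simplicity, so topology is preserved
// and the result stays roughly centered. Curve endpoints (exactly one
// foreground neighbour) and isolated voxels are never removed.

static const int NB27_OFF[27][3] = {
  {-1,-1,-1},{0,-1,-1},{1,-1,-1},{-1,0,-1},{0,0,-1},{1,0,-1},{-1,1,-1},{0,1,-1},{1,1,-1},
  {-1,-1,0},{0,-1,0},{1,-1,0},{-1,0,0},{0,0,0},{1,0,0},{-1,1,0},{0,1,0},{1,1,0},
  {-1,-1,1},{0,-1,1},{1,-1,1},{-1,0,1},{0,0,1},{1,0,1},{-1,1,1},{0,1,1},{1,1,1}
};
// index in 0..26 for offset (dz,dy,dx): (dz+1) + 3*(dy+1) + 9*(dx+1)
static inline int nb_idx(int dz, int dy, int dx) {
  return (dz + 1) + 3 * (dy + 1) + 9 * (dx + 1);
}

// gather 3x3x3 occupancy (out of bounds = background)
static inline void gather(const int* m, int nz, int ny, int nx,
                          int z, int y, int x, bool nb[27]) {
  for (int k = 0; k < 27; ++k) {
    int zz = z + NB27_OFF[k][0], yy = y + NB27_OFF[k][1], xx = x + NB27_OFF[k][2];
    if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
      nb[k] = false;
    else
      nb[k] = m[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)] != 0;
  }
}

static int count_fg_neighbours(const bool nb[27]) {
  int c = 0;
  for (int k = 0; k < 27; ++k)
    if (k != 13 && nb[k]) ++c;
  return c;
}

// condition (a): one 26-component of foreground within N26*
static bool one_fg_component26(const bool nb[27]) {
  bool seen[27] = {false};
  int ncomp = 0;
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++ncomp;
    if (ncomp > 1) return false;
    // BFS over 26-adjacency inside the 3x3x3 box (center excluded)
    int stack[27], top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int cur = stack[--top];
      int cz = NB27_OFF[cur][0], cy = NB27_OFF[cur][1], cx = NB27_OFF[cur][2];
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int nz2 = cz + dz, ny2 = cy + dy, nx2 = cx + dx;
            if (nz2 < -1 || nz2 > 1 || ny2 < -1 || ny2 > 1 || nx2 < -1 || nx2 > 1)
              continue;
            int j = nb_idx(nz2, ny2, nx2);
            if (j == 13 || seen[j] || !nb[j]) continue;
            seen[j] = true;
            stack[top++] = j;
          }
    }
  }
  return ncomp == 1;
}

// condition (b): background 6-components within N18 touching a face neighbour
static bool one_bg_component6(const bool nb[27]) {
  // N18 membership: at most two non-zero offsets
  auto in18 = [](int k) {
    int a = NB27_OFF[k][0] != 0, b = NB27_OFF[k][1] != 0, c = NB27_OFF[k][2] != 0;
    return (a + b + c) <= 2 && k != 13;
  };
  bool seen[27] = {false};
  int ncomp = 0;
  static const int FACE[6] = {4, 22, 10, 16, 12, 14}; // the 6 face neighbours
  for (int fi = 0; fi < 6; ++fi) {
    int s = FACE[fi];
    if (nb[s] || seen[s]) continue; // must be background, unvisited
    ++ncomp;
    if (ncomp > 1) return false;
    int stack[27], top = 0;
    stack[top++] = s;
    seen[s] = true;
    while (top > 0) {
      int cur = stack[--top];
      int cz = NB27_OFF[cur][0], cy = NB27_OFF[cur][1], cx = NB27_OFF[cur][2];
      static const int D6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int d = 0; d < 6; ++d) {
        int nz2 = cz + D6[d][0], ny2 = cy + D6[d][1], nx2 = cx + D6[d][2];
        if (nz2 < -1 || nz2 > 1 || ny2 < -1 || ny2 > 1 || nx2 < -1 || nx2 > 1)
          continue;
        int j = nb_idx(nz2, ny2, nx2);
        if (j == 13 || seen[j] || nb[j] || !in18(j)) continue;
        seen[j] = true;
        stack[top++] = j;
      }
    }
  }
  return ncomp == 1;
}

static inline bool is_simple(const bool nb[27]) {
  return one_fg_component26(nb) && one_bg_component6(nb);
}

// [[Rcpp::export]]
LogicalVector thin3d_cpp(LogicalVector mask, IntegerVector dim) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t N = (R_xlen_t)nz * ny * nx;
  std::vector<int> m(N);
  std::vector<R_xlen_t> active;
  for (R_xlen_t i = 0; i < N; ++i) {
    m[i] = mask[i] ? 1 : 0;
    if (m[i]) active.push_back(i);
  }
  // directional border offsets in (dz,dy,dx)
  static const int DIR[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  bool nb[27];
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      std::vector<R_xlen_t> cand;
      for (size_t ii = 0; ii < active.size(); ++ii) {
        R_xlen_t i = active[ii];
        if (!m[i]) continue;
        int x = (int)(i / ((R_xlen_t)nz * ny));
        int rem = (int)(i - (R_xlen_t)nz * ny * x);
        int y = rem / nz, z = rem % nz;
        int zz = z + DIR[d][0], yy = y + DIR[d][1], xx = x + DIR[d][2];
        bool border = (zz < 0 || zz >= nz || yy < 0 || yy >= ny ||
                       xx < 0 || xx >= nx) ||
                      !m[zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx)];
        if (!border) continue;
        gather(m.data(), nz, ny, nx, z, y, x, nb);
        int nc = count_fg_neighbours(nb);
        if (nc <= 1) continue; // endpoint or isolated
        if (is_simple(nb)) cand.push_back(i);
      }
      // sequential re-check and delete
      for (size_t ii = 0; ii < cand.size(); ++ii) {
        R_xlen_t i = cand[ii];
        int x = (int)(i / ((R_xlen_t)nz * ny));
        int rem = (int)(i - (R_xlen_t)nz * ny * x);
        int y = rem / nz, z = rem % nz;
        gather(m.data(), nz, ny, nx, z, y, x, nb);
        int nc = count_fg_neighbours(nb);
        if (nc <= 1) continue;
        if (!is_simple(nb)) continue;
        m[i] = 0;
        changed = true;
      }
    }
    // compact active set
    if (changed) {
      std::vector<R_xlen_t> keep;
      keep.reserve(active.size());
      for (size_t ii = 0; ii < active.size(); ++ii)
        if (m[active[ii]]) keep.push_back(active[ii]);
      active.swap(keep);
    }
  }
  LogicalVector out(N);
  for (R_xlen_t i = 0; i < N; ++i) out[i] = m[i] != 0;
  return out;
}
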