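#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <cfloat>

using namespace Rcpp;

// Uniform-grid nearest-neighbour search between 3-D point sets.
// Cells are hashed; the query expands Chebyshev rings until the ring
// lower bound exceeds the best distance found so far.

static inline long long cell_key(int ix, int iy, int iz) {
  // grid extents are bounded well below 2^20 cells per axis
  return (((long long)ix) << 42) ^ (((long long)iy) << 21) ^ (long long)iz;
}

// [[Rcpp::export]]
List nn_lookup_cpp(NumericMatrix query, NumericMatrix ref) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (nr == 0) stop("reference point set is empty");

  double lo[3], hi[3];
  for (int d = 0; d < 3; ++d) { lo[d] = R_PosInf; hi[d] = R_NegInf; }
  for (int i = 0; i < nr; ++i)
    for (int d = 0; d < 3; ++d) {
      double v = ref(i, d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  double ext = 0.0;
  for (int d = 0; d < 3; ++d) ext = std::max(ext, hi[d] - lo[d]);
  // aim for a handful of points per occupied cell
  double cell = std::cbrt(std::max(ext * ext * ext, 1e-12) / nr) * 2.0;
  if (!(cell > 0) || !R_finite(cell)) cell = 1.0;

  std::unordered_map<long long, std::vector<int> > bins;
  bins.reserve(nr);
  for (int i = 0; i < nr; ++i) {
    int ix = (int)std::floor((ref(i, 0) - lo[0]) / cell);
    int iy = (int)std::floor((ref(i, 1) - lo[1]) / cell);
    int iz = (int)std::floor((ref(i, 2) - lo[2]) / cell);
    bins[cell_key(ix, iy, iz)].push_back(i);
  }
  int max_ring = (int)std::ceil(ext / cell) + 2;

  NumericVector dist(nq);
  IntegerVector index(nq);
  for (int q = 0; q < nq; ++q) {
    double px = query(q, 0), py = query(q, 1), pz = query(q, 2);
    int cx = (int)std::floor((px - lo[0]) / cell);
    int cy = (int)std::floor((py - lo[1]) / cell);
    int cz = (int)std::floor((pz - lo[2]) / cell);
    double best = DBL_MAX;
    int best_i = -1;
    for (int ring = 0; ring <= max_ring || best_i < 0; ++ring) {
      // any point in ring k is at distance >= (k-1)*cell from the query
      if (best_i >= 0 && best <= (double)(ring - 1) * cell) break;
      for (int ix = cx - ring; ix <= cx + ring; ++ix)
        for (int iy = cy - ring; iy <= cy + ring; ++iy)
          for (int iz = cz - ring; iz <= cz + ring; ++iz) {
            if (std::max(std::abs(ix - cx),
                std::max(std::abs(iy - cy), std::abs(iz - cz))) != ring)
              continue;
            auto it = bins.find(cell_key(ix, iy, iz));
            if (it == bins.end()) continue;
            for (int i : it->second) {
              double dx = ref(i, 0) - px, dy = ref(i, 1) - py,
                     dz = ref(i, 2) - pz;
              double d2 = dx * dx + dy * dy + dz * dz;
              if (d2 < best) { best = d2; best_i = i; }
            }
          }
      if (ring > max_ring + 4096) stop("nearest-neighbour search failed");
    }
    dist[q] = std::sqrt(best);
    index[q] = best_i + 1;
  }
  return List::create(_["dist"] = dist, _["index"] = index);
}

// 26-connected flood fill on a 3-D logical mask from a seed voxel.
// Returns the connected component containing the seed.

// [[Rcpp::export]]
LogicalVector flood_fill26_cpp(LogicalVector mask, IntegerVector dims,
                               int seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long long n = (long long)nx * ny * nz;
  if (mask.size() != n) stop("mask length does not match dims");
  if (seed < 1 || seed > n) stop("seed voxel outside the grid");
  LogicalVector out(n, false);
  if (!mask[seed - 1]) stop("seed voxel is not inside the mask");

  std::vector<int> stack;
  stack.reserve(4096);
  stack.push_back(seed - 1);
  out[seed - 1] = true;
  const long long sxy = (long long)nx * ny;
  while (!stack.empty()) {
    int v = stack.back();
    stack.pop_back();
    int iz = v / sxy, rem = v % sxy, iy = rem / nx, ix = rem % nx;
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int jx = ix + dx, jy = iy + dy, jz = iz + dz;
          if (jx < 0 || jx >= nx || jy < 0 || jy >= ny || jz < 0 || jz >= nz)
            continue;
          long long j = jx + (long long)jy * nx + (long long)jz * sxy;
          if (mask[j] && !out[j]) {
            out[j] = true;
            stack.push_back((int)j);
          }
        }
  }
  return out;
}
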