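#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// Neighbor offsets for a given 3D connectivity (6 = faces, 18 = faces+edges,
// 26 = faces+edges+corners).
static std::vector<std::array<int, 3>> neighbor_offsets(int connectivity) {
  std::vector<std::array<int, 3>> off;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int m = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (m == 0) continue;
        if (connectivity == 6 && m > 1) continue;
        if (connectivity == 18 && m > 2) continue;
        off.push_back({dx, dy, dz});
      }
  return off;
}

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerVector label_components_cpp(LogicalVector x, IntegerVector dims,
                                   int connectivity) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (x.size() != n) stop("array length does not match dims");
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  IntegerVector lab(n, 0);
  std::vector<std::array<int, 3>> off = neighbor_offsets(connectivity);
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!x[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      R_xlen_t v = q.front(); q.pop();
      int vx = (int)(v % nx);
      int vy = (int)((v / nx) % ny);
      int vz = (int)(v / ((R_xlen_t)nx * ny));
      for (auto &o : off) {
        int ax = vx + o[0], ay = vy + o[1], az = vz + o[2];
        if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
          continue;
        R_xlen_t w = (R_xlen_t)az * nx * ny + (R_xlen_t)ay * nx + ax;
        if (x[w] && lab[w] == 0) { lab[w] = next; q.push(w); }
      }
    }
  }
  return lab;
}

// Random-walk region growing: starting from `start` (1-based linear index),
// repeatedly absorb a uniformly chosen voxel from the current boundary until
// `target_size` voxels are lesioned. Growth is face-connected, so the result
// is always a single connected component. Uses R's RNG (unif_rand), so
// set.seed() governs reproducibility.
// [[Rcpp::export(name = ".grow_lesion_cpp")]]
IntegerVector grow_lesion_cpp(IntegerVector dims, int start, int target_size) {
  if (dims.size() != 3) stop("dims must have length 3");
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  if (start < 1 || start > n) stop("start voxel outside grid");
  if (target_size < 1) stop("target_size must be >= 1");
  if (target_size > n) target_size = (int)n;
  std::vector<char> state(n, 0);  // 0 free, 1 in region, 2 in boundary
  std::vector<int> region;
  std::vector<int> boundary;
  region.reserve(target_size);
  const int off[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
  RNGScope scope;
  R_xlen_t cur = start - 1;
  state[cur] = 1;
  region.push_back((int)cur);
  while ((int)region.size() < target_size) {
    // push free face-neighbors of the newest voxel onto the boundary
    int vx = (int)(cur % nx);
    int vy = (int)((cur / nx) % ny);
    int vz = (int)(cur / ((R_xlen_t)nx * ny));
    for (int k = 0; k < 6; ++k) {
      int ax = vx + off[k][0], ay = vy + off[k][1], az = vz + off[k][2];
      if (ax < 0 || ax >= nx || ay < 0 || ay >= ny || az < 0 || az >= nz)
        continue;
      R_xlen_t w = (R_xlen_t)az * nx * ny + (R_xlen_t)ay * nx + ax;
      if (state[w] == 0) { state[w] = 2; boundary.push_back((int)w); }
    }
    if (boundary.empty()) break;  // grid exhausted
    int pick = (int)(unif_rand() * boundary.size());
    if (pick >= (int)boundary.size()) pick = (int)boundary.size() - 1;
    cur = boundary[pick];
    boundary[pick] = boundary.back();
    boundary.pop_back();
    state[cur] = 1;
    region.push_back((int)cur);
  }
  IntegerVector out(region.size());
  for (size_t i = 0; i < region.size(); ++i) out[i] = region[i] + 1;
  return out;
}
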