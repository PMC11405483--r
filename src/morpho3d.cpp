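// 3D morphology primitives used by the segmentation stage.
// Volumes are passed as flat vectors in R's column-major order with dims
// (nx, ny, nz); all routines treat out-of-bounds as background.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <array>
#include <cmath>

using namespace Rcpp;

namespace {

struct Grid {
  int nx, ny, nz;
  Grid(IntegerVector dim) : nx(dim[0]), ny(dim[1]), nz(dim[2]) {}
  inline R_xlen_t idx(int x, int y, int z) const {
    return (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
  }
  inline bool inside(int x, int y, int z) const {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  }
};

// neighbour offsets for the requested connectivity (6 or 26)
void neighbour_offsets(int connectivity, std::vector<std::array<int, 3>>& off) {
  off.clear();
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if (connectivity == 6 && manh > 1) continue;
        off.push_back({dx, dy, dz});
      }
}

} // namespace

// [[Rcpp::export(name = ".cc_label_3d")]]
IntegerVector cc_label_3d(LogicalVector mask, IntegerVector dim,
                          int connectivity = 26) {
  Grid g(dim);
  R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(connectivity, off);

  int current = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < n; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++current;
    labels[start] = current;
    stack.clear();
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t v = stack.back();
      stack.pop_back();
      int z = (int)(v / ((R_xlen_t)g.nx * g.ny));
      R_xlen_t rem = v - (R_xlen_t)z * g.nx * g.ny;
      int y = (int)(rem / g.nx), x = (int)(rem % g.nx);
      for (auto& d : off) {
        int xx = x + d[0], yy = y + d[1], zz = z + d[2];
        if (!g.inside(xx, yy, zz)) continue;
        R_xlen_t w = g.idx(xx, yy, zz);
        if (mask[w] && labels[w] == 0) {
          labels[w] = current;
          stack.push_back(w);
        }
      }
    }
  }
  return labels;
}

// Anisotropic chamfer distance (26-neighbour weights = physical step length),
// distance of foreground voxels to the nearest background voxel.
// [[Rcpp::export(name = ".chamfer_dist_3d")]]
NumericVector chamfer_dist_3d(LogicalVector mask, IntegerVector dim,
                              NumericVector spacing) {
  Grid g(dim);
  R_xlen_t n = mask.size();
  const double INF = std::numeric_limits<double>::infinity();
  NumericVector dist(n);
  for (R_xlen_t i = 0; i < n; ++i) dist[i] = mask[i] ? INF : 0.0;

  std::vector<std::array<int, 3>> off;
  neighbour_offsets(26, off);
  std::vector<double> w(off.size());
  for (size_t k = 0; k < off.size(); ++k) {
    double dx = off[k][0] * spacing[0], dy = off[k][1] * spacing[1],
           dz = off[k][2] * spacing[2];
    w[k] = std::sqrt(dx * dx + dy * dy + dz * dz);
  }

  // forward pass then backward pass; each uses the half of the neighbourhood
  // already visited in its scan order
  for (int pass = 0; pass < 2; ++pass) {
    bool forward = pass == 0;
    for (int zi = 0; zi < g.nz; ++zi) {
      int z = forward ? zi : g.nz - 1 - zi;
      for (int yi = 0; yi < g.ny; ++yi) {
        int y = forward ? yi : g.ny - 1 - yi;
        for (int xi = 0; xi < g.nx; ++xi) {
          int x = forward ? xi : g.nx - 1 - xi;
          R_xlen_t v = g.idx(x, y, z);
          if (!mask[v]) continue;
          double best = dist[v];
          for (size_t k = 0; k < off.size(); ++k) {
            // visited half-space: lexicographically "before" in scan order
            int dzo = forward ? off[k][2] : -off[k][2];
            int dyo = forward ? off[k][1] : -off[k][1];
            int dxo = forward ? off[k][0] : -off[k][0];
            bool before = dzo < 0 || (dzo == 0 && (dyo < 0 || (dyo == 0 && dxo < 0)));
            if (!before) continue;
            int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
            double dn = g.inside(xx, yy, zz) ? dist[g.idx(xx, yy, zz)] : 0.0;
            if (dn + w[k] < best) best = dn + w[k];
          }
          dist[v] = best;
        }
      }
    }
  }
  return dist;
}

// Seeded watershed by priority flood: grow seed labels outward over `mask`
// in order of decreasing `priority` (typically the distance transform).
// [[Rcpp::export(name = ".watershed_seeded_3d")]]
IntegerVector watershed_seeded_3d(NumericVector priority, IntegerVector seeds,
                                  LogicalVector mask, IntegerVector dim,
                                  int connectivity = 26) {
  Grid g(dim);
  R_xlen_t n = mask.size();
  IntegerVector labels(n, 0);
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(connectivity, off);

  typedef std::pair<double, R_xlen_t> Node;
  std::priority_queue<Node> pq; // max-heap on priority
  for (R_xlen_t i = 0; i < n; ++i) {
    if (seeds[i] > 0 && mask[i]) {
      labels[i] = seeds[i];
      pq.push(Node(priority[i], i));
    }
  }
  while (!pq.empty()) {
    R_xlen_t v = pq.top().second;
    pq.pop();
    int lab = labels[v];
    int z = (int)(v / ((R_xlen_t)g.nx * g.ny));
    R_xlen_t rem = v - (R_xlen_t)z * g.nx * g.ny;
    int y = (int)(rem / g.nx), x = (int)(rem % g.nx);
    for (auto& d : off) {
      int xx = x + d[0], yy = y + d[1], zz = z + d[2];
      if (!g.inside(xx, yy, zz)) continue;
      R_xlen_t w = g.idx(xx, yy, zz);
      if (mask[w] && labels[w] == 0) {
        labels[w] = lab;
        pq.push(Node(priority[w], w));
      }
    }
  }
  return labels;
}

// Voxels that are >= all of their 26 neighbours (within mask) and above
// `threshold`; plateaus are returned whole and collapsed by the caller.
// [[Rcpp::export(name = ".local_maxima_3d")]]
LogicalVector local_maxima_3d(NumericVector vol, LogicalVector mask,
                              IntegerVector dim, double threshold) {
  Grid g(dim);
  R_xlen_t n = vol.size();
  LogicalVector out(n, false);
  std::vector<std::array<int, 3>> off;
  neighbour_offsets(26, off);
  for (int z = 0; z < g.nz; ++z)
    for (int y = 0; y < g.ny; ++y)
      for (int x = 0; x < g.nx; ++x) {
        R_xlen_t v = g.idx(x, y, z);
        if (!mask[v] || vol[v] <= threshold) continue;
        bool is_max = true;
        for (auto& d : off) {
          int xx = x + d[0], yy = y + d[1], zz = z + d[2];
          if (!g.inside(xx, yy, zz)) continue;
          R_xlen_t w = g.idx(xx, yy, zz);
          if (mask[w] && vol[w] > vol[v]) { is_max = false; break; }
        }
        if (is_max) out[v] = true;
      }
  return out;
}
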