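// 3D image primitives used by the segmentation pipeline.
// All volumes are R arrays with dim = (nz, ny, nx), column-major,
// so linear index = z + nz * (y + ny * x).

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <map>
#include <tuple>
#include <algorithm>

using namespace Rcpp;

static inline int reflect_index(int i, int n) {
  // mirror boundary without repeating the edge sample twice in a row
  if (n == 1) return 0;
  int period = 2 * n - 2;
  i = i % period;
  if (i < 0) i += period;
  return (i < n) ? i : period - i;
}

// Separable Gaussian smoothing with per-axis sigma (voxel units).
// sigma of 0 (or < 1e-8) skips that axis. Mirror boundary handling.
// [[Rcpp::export]]
NumericVector cpp_gaussian_smooth(NumericVector vol, NumericVector sigma) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("volume must be a 3-d array");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const int n[3] = {nz, ny, nx};
  const R_xlen_t total = (R_xlen_t)nz * ny * nx;
  std::vector<double> cur(vol.begin(), vol.end());
  std::vector<double> out(total);

  for (int axis = 0; axis < 3; axis++) {
    double s = sigma[axis];
    if (s < 1e-8 || n[axis] == 1) continue;
    int radius = (int)std::ceil(4.0 * s);
    std::vector<double> k(2 * radius + 1);
    double ksum = 0.0;
    for (int i = -radius; i <= radius; i++) {
      k[i + radius] = std::exp(-0.5 * (double)i * i / (s * s));
      ksum += k[i + radius];
    }
    for (double &v : k) v /= ksum;

    // convolve every 1-d line along this axis
    R_xlen_t stride = (axis == 0) ? 1 : (axis == 1) ? nz : (R_xlen_t)nz * ny;
    int len = n[axis];
    std::vector<double> line(len);
    // enumerate line base indices: all voxels with coordinate 0 on `axis`
    std::vector<R_xlen_t> bases;
    if (axis == 0) {
      bases.reserve((R_xlen_t)ny * nx);
      for (R_xlen_t j = 0; j < (R_xlen_t)ny * nx; j++) bases.push_back(j * nz);
    } else if (axis == 1) {
      bases.reserve((R_xlen_t)nz * nx);
      for (int x = 0; x < nx; x++)
        for (int z = 0; z < nz; z++)
          bases.push_back(z + (R_xlen_t)nz * ny * x);
    } else {
      bases.reserve((R_xlen_t)nz * ny);
      for (R_xlen_t j = 0; j < (R_xlen_t)nz * ny; j++) bases.push_back(j);
    }
    for (R_xlen_t b : bases) {
      for (int p = 0; p < len; p++) line[p] = cur[b + (R_xlen_t)p * stride];
      for (int p = 0; p < len; p++) {
        double acc = 0.0;
        if (p >= radius && p + radius < len) {
          const double *lp = &line[p - radius];
          for (int i = 0; i <= 2 * radius; i++) acc += k[i] * lp[i];
        } else {
          for (int i = -radius; i <= radius; i++) {
            acc += k[i + radius] * line[reflect_index(p + i, len)];
          }
        }
        out[b + (R_xlen_t)p * stride] = acc;
      }
    }
    cur.swap(out);
  }

  NumericVector res(cur.begin(), cur.end());
  res.attr("dim") = dims;
  return res;
}

static int neighbor_offsets(int connectivity, const int nz, const int ny,
                            int dz[], int dy[], int dx[]) {
  int m = 0;
  if (connectivity == 6) {
    int d6[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
    for (int i = 0; i < 6; i++) { dz[m]=d6[i][0]; dy[m]=d6[i][1]; dx[m]=d6[i][2]; m++; }
  } else {
    for (int a = -1; a <= 1; a++)
      for (int b = -1; b <= 1; b++)
        for (int c = -1; c <= 1; c++) {
          if (a == 0 && b == 0 && c == 0) continue;
          dz[m] = a; dy[m] = b; dx[m] = c; m++;
        }
  }
  (void)nz; (void)ny;
  return m;
}

// Connected-component labeling of a binary mask (non-zero = foreground).
// connectivity: 6 or 26. Labels assigned in raster-scan order from 1.
// [[Rcpp::export]]
IntegerVector cpp_label_components(IntegerVector mask, int connectivity) {
  IntegerVector dims = mask.attr("dim");
  if (dims.size() != 3) stop("mask must be a 3-d array");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t total = (R_xlen_t)nz * ny * nx;
  IntegerVector labels(total, 0);
  labels.attr("dim") = dims;
  int dz[26], dy[26], dx[26];
  int m = neighbor_offsets(connectivity, nz, ny, dz, dy, dx);

  int next_label = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t start = 0; start < total; start++) {
    if (mask[start] == 0 || labels[start] != 0) continue;
    next_label++;
    labels[start] = next_label;
    stack.push_back(start);
    while (!stack.empty()) {
      R_xlen_t idx = stack.back(); stack.pop_back();
      int z = (int)(idx % nz);
      int y = (int)((idx / nz) % ny);
      int x = (int)(idx / ((R_xlen_t)nz * ny));
      for (int i = 0; i < m; i++) {
        int zz = z + dz[i], yy = y + dy[i], xx = x + dx[i];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
        R_xlen_t nidx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (mask[nidx] != 0 && labels[nidx] == 0) {
          labels[nidx] = next_label;
          stack.push_back(nidx);
        }
      }
    }
  }
  return labels;
}

struct WsNode {
  double height;
  unsigned long order;
  R_xlen_t idx;
};
struct WsCompare {
  bool operator()(const WsNode &a, const WsNode &b) const {
    if (a.height != b.height) return a.height > b.height;   // min-heap on height
    return a.order > b.order;                               // FIFO tie-break
  }
};

// Seeded watershed by priority flooding. Floods ascending `height` from
// labeled seed voxels, constrained to `mask`. Foreground voxels not
// reachable from any seed stay 0. 26-connectivity. `max_height` gives a
// per-label ceiling: a voxel joins label l only while height <=
// max_height[l-1] (pass +Inf for an unconstrained flood).
// [[Rcpp::export]]
IntegerVector cpp_watershed_seeded(NumericVector height, IntegerVector seeds,
                                   LogicalVector mask,
                                   NumericVector max_height) {
  IntegerVector dims = height.attr("dim");
  if (dims.size() != 3) stop("height must be a 3-d array");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t total = (R_xlen_t)nz * ny * nx;
  if (seeds.size() != total || mask.size() != total)
    stop("seeds and mask must match the height volume");

  IntegerVector labels(total, 0);
  labels.attr("dim") = dims;
  int dz[26], dy[26], dx[26];
  int m = neighbor_offsets(26, nz, ny, dz, dy, dx);

  std::priority_queue<WsNode, std::vector<WsNode>, WsCompare> pq;
  unsigned long order = 0;
  for (R_xlen_t i = 0; i < total; i++) {
    if (seeds[i] > 0 && mask[i]) {
      labels[i] = seeds[i];
      pq.push({height[i], order++, i});
    }
  }
  while (!pq.empty()) {
    WsNode node = pq.top(); pq.pop();
    R_xlen_t idx = node.idx;
    int z = (int)(idx % nz);
    int y = (int)((idx / nz) % ny);
    int x = (int)(idx / ((R_xlen_t)nz * ny));
    int lab = labels[idx];
    for (int i = 0; i < m; i++) {
      int zz = z + dz[i], yy = y + dy[i], xx = x + dx[i];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t nidx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (!mask[nidx] || labels[nidx] != 0) continue;
      if (lab <= max_height.size() && height[nidx] > max_height[lab - 1]) continue;
      labels[nidx] = lab;
      pq.push({height[nidx], order++, nidx});
    }
  }
  return labels;
}

// Local maxima: voxel value >= all 26 neighbors (in-bounds only).
// [[Rcpp::export]]
LogicalVector cpp_local_maxima(NumericVector vol) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("volume must be a 3-d array");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t total = (R_xlen_t)nz * ny * nx;
  LogicalVector out(total);
  out.attr("dim") = dims;
  int dz[26], dy[26], dx[26];
  int m = neighbor_offsets(26, nz, ny, dz, dy, dx);
  for (R_xlen_t idx = 0; idx < total; idx++) {
    double v = vol[idx];
    int z = (int)(idx % nz);
    int y = (int)((idx / nz) % ny);
    int x = (int)(idx / ((R_xlen_t)nz * ny));
    bool is_max = true;
    for (int i = 0; i < m && is_max; i++) {
      int zz = z + dz[i], yy = y + dy[i], xx = x + dx[i];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) continue;
      R_xlen_t nidx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (vol[nidx] > v) is_max = false;
    }
    out[idx] = is_max;
  }
  return out;
}

// Grayscale dilation with a 3x3x3 structuring element (26-neighborhood
// max, including self). Used for scale-space maxima detection.
// [[Rcpp::export]]
NumericVector cpp_max_filter(NumericVector vol) {
  IntegerVector dims = vol.attr("dim");
  if (dims.size() != 3) stop("volume must be a 3-d array");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t total = (R_xlen_t)nz * ny * nx;
  NumericVector out(total);
  out.attr("dim") = dims;
  for (R_xlen_t idx = 0; idx < total; idx++) {
    int z = (int)(idx % nz);
    int y = (int)((idx / nz) % ny);
    int x = (int)(idx / ((R_xlen_t)nz * ny));
    double m = vol[idx];
    for (int a = std::max(0, z - 1); a <= std::min(nz - 1, z + 1); a++)
      for (int b = std::max(0, y - 1); b <= std::min(ny - 1, y + 1); b++)
        for (int c = std::max(0, x - 1); c <= std::min(nx - 1, x + 1); c++) {
          double v = vol[a + (R_xlen_t)nz * (b + (R_xlen_t)ny * c)];
          if (v > m) m = v;
        }
    out[idx] = m;
  }
  return out;
}

static double sphere_overlap_frac(double r1, double r2, double d) {
  double rmin = std::min(r1, r2);
  if (rmin <= 0) return 1.0;
  if (d >= r1 + r2) return 0.0;
  if (d <= std::fabs(r1 - r2)) return 1.0;
  double lens = M_PI * std::pow(r1 + r2 - d, 2.0) *
    (d * d + 2.0 * d * (r1 + r2) - 3.0 * std::pow(r1 - r2, 2.0)) / (12.0 * d);
  return lens / ((4.0 / 3.0) * M_PI * rmin * rmin * rmin);
}

// Prune overlapping blobs: pos (n x 3, physical um), radius r (um),
// response. Blobs are visited strongest-response-first; a surviving blob
// removes any overlapping blob of weaker (or equal, later-indexed)
// response. Removing by response rather than radius keeps the detected
// set monotone in the detection threshold: a weak blob that only appears
// at low thresholds can never evict a strong one. Uses a uniform grid so
// only nearby pairs are tested.
// [[Rcpp::export]]
LogicalVector cpp_prune_blobs(NumericMatrix pos, NumericVector r,
                              NumericVector response, double overlap) {
  int n = pos.nrow();
  LogicalVector keep(n, true);
  if (n <= 1 || overlap > 1.0) return keep;
  double rmax = 0.0;
  for (int i = 0; i < n; i++) rmax = std::max(rmax, r[i]);
  double cell = std::max(2.0 * rmax, 1e-9);
  double mins[3];
  for (int a = 0; a < 3; a++) {
    mins[a] = pos(0, a);
    for (int i = 1; i < n; i++) mins[a] = std::min(mins[a], pos(i, a));
  }
  auto cell_of = [&](int i, int a) {
    return (long long)std::floor((pos(i, a) - mins[a]) / cell);
  };
  std::map<std::tuple<long long, long long, long long>, std::vector<int> > grid;
  for (int i = 0; i < n; i++) {
    grid[std::make_tuple(cell_of(i, 0), cell_of(i, 1), cell_of(i, 2))].push_back(i);
  }
  // visit blobs strongest-first so removals are deterministic
  std::vector<int> order(n);
  for (int i = 0; i < n; i++) order[i] = i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (response[a] != response[b]) return response[a] > response[b];
    return a < b;
  });
  for (int oi = 0; oi < n; oi++) {
    int i = order[oi];
    if (!keep[i]) continue;
    long long ci0 = cell_of(i, 0), ci1 = cell_of(i, 1), ci2 = cell_of(i, 2);
    for (long long a = ci0 - 1; a <= ci0 + 1; a++)
      for (long long b = ci1 - 1; b <= ci1 + 1; b++)
        for (long long c = ci2 - 1; c <= ci2 + 1; c++) {
          auto it = grid.find(std::make_tuple(a, b, c));
          if (it == grid.end()) continue;
          for (int j : it->second) {
            if (j == i || !keep[j] || !keep[i]) continue;
            double dx = 0.0;
            for (int ax = 0; ax < 3; ax++) {
              double dd = pos(i, ax) - pos(j, ax);
              dx += dd * dd;
            }
            double frac = sphere_overlap_frac(r[i], r[j], std::sqrt(dx));
            if (frac >= overlap) {
              if (response[j] > response[i] ||
                  (response[j] == response[i] && j < i)) continue;
              keep[j] = false;
            }
          }
        }
  }
  return keep;
}

// Boundary voxels of labeled regions: label > 0 and some 6-neighbor has a
// different label (or the voxel touches the array edge).
// [[Rcpp::export]]
LogicalVector cpp_label_boundary(IntegerVector labels) {
  IntegerVector dims = labels.attr("dim");
  if (dims.size() != 3) stop("labels must be a 3-d array");
  const int nz = dims[0], ny = dims[1], nx = dims[2];
  const R_xlen_t total = (R_xlen_t)nz * ny * nx;
  LogicalVector out(total);
  out.attr("dim") = dims;
  int dz[6], dy[6], dx[6];
  int m = neighbor_offsets(6, nz, ny, dz, dy, dx);
  for (R_xlen_t idx = 0; idx < total; idx++) {
    int lab = labels[idx];
    if (lab == 0) { out[idx] = false; continue; }
    int z = (int)(idx % nz);
    int y = (int)((idx / nz) % ny);
    int x = (int)(idx / ((R_xlen_t)nz * ny));
    bool boundary = false;
    for (int i = 0; i < m && !boundary; i++) {
      int zz = z + dz[i], yy = y + dy[i], xx = x + dx[i];
      if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx) {
        // treat z-extent-1 arrays as planar: out-of-range along a
        // degenerate axis is not a boundary
        int extent = (i < 2) ? nz : (i < 4) ? ny : nx;
        if (extent > 1) boundary = true;
        continue;
      }
      R_xlen_t nidx = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
      if (labels[nidx] != lab) boundary = true;
    }
    out[idx] = boundary;
  }
  return out;
}
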