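#include <Rcpp.h>
#include <queue>
#include <vector>
#include <map>
#include <cmath>

using namespace Rcpp;

// 26-neighbourhood offsets, filled once
static int OFF[26][3];
static bool off_init = false;
static void init_offsets() {
  if (off_init) return;
  int n = 0;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        OFF[n][0] = dx; OFF[n][1] = dy; OFF[n][2] = dz; ++n;
      }
  off_init = true;
}

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// Separable 3-D Gaussian convolution with reflect padding.
// sigma is per-axis in voxel units; kernel radius = ceil(4*sigma).
// ---------------------------------------------------------------------------

static void conv_axis(std::vector<double>& v, int nx, int ny, int nz,
                      int axis, double sigma) {
  if (sigma <= 0) return;
  int r = (int)std::ceil(4.0 * sigma);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-0.5 * (double)i * i / (sigma * sigma));
    s += k[i + r];
  }
  for (double& kv : k) kv /= s;

  int n = (axis == 0) ? nx : (axis == 1) ? ny : nz;
  std::vector<double> line(n), out(n);
  int n0 = (axis == 0) ? ny : nx;
  int n1 = (axis == 2) ? ny : nz;

  for (int a = 0; a < n0; ++a) {
    for (int b = 0; b < n1; ++b) {
      for (int i = 0; i < n; ++i) {
        int x = (axis == 0) ? i : a;
        int y = (axis == 0) ? a : (axis == 1) ? i : b;
        int z = (axis == 2) ? i : b;
        line[i] = v[lin(x, y, z, nx, ny)];
      }
      for (int i = 0; i < n; ++i) {
        double acc = 0.0;
        for (int j = -r; j <= r; ++j) {
          int idx = i + j;
          // reflect (mirror without repeating the edge sample), as in
          // scipy.ndimage mode="reflect" for n > 1
          if (n == 1) idx = 0;
          else {
            while (idx < 0 || idx >= n) {
              if (idx < 0) idx = -idx - 1;
              if (idx >= n) idx = 2 * n - idx - 1;
            }
          }
          acc += k[j + r] * line[idx];
        }
        out[i] = acc;
      }
      for (int i = 0; i < n; ++i) {
        int x = (axis == 0) ? i : a;
        int y = (axis == 0) ? a : (axis == 1) ? i : b;
        int z = (axis == 2) ? i : b;
        v[lin(x, y, z, nx, ny)] = out[i];
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss3d(NumericVector vol, IntegerVector dim,
                          NumericVector sigma) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  conv_axis(v, nx, ny, nz, 0, sigma[0]);
  conv_axis(v, nx, ny, nz, 1, sigma[1]);
  conv_axis(v, nx, ny, nz, 2, sigma[2]);
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Flooding watershed, 26-connectivity.
// Basins are seeded at regional maxima (equal-value plateaus with no higher
// masked neighbour); remaining masked voxels are flooded in descending SUV
// order; a voxel reachable from several basins (a watershed-line voxel) is
// assigned to the neighbouring basin with the higher basin maximum.
// ---------------------------------------------------------------------------

struct QItem {
  double val;
  long long ord;
  int idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.val != b.val) return a.val < b.val;   // max-heap on value
    return a.ord > b.ord;                        // FIFO among equals
  }
};

// [[Rcpp::export]]
IntegerVector cpp_watershed(NumericVector vol, LogicalVector mask,
                            IntegerVector dim) {
  init_offsets();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  IntegerVector labels(n, 0);
  std::vector<char> inq(n, 0);
  std::vector<double> basin_max;   // basin_max[label-1]
  basin_max.push_back(0.0);        // dummy so labels index from 1 cleanly
  basin_max.clear();

  // pass 1: regional-maximum plateaus as seeds
  std::vector<char> visited(n, 0);
  std::vector<int> stack, comp;
  int next_label = 0;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        if (!mask[i] || visited[i]) continue;
        double v0 = vol[i];
        bool is_max = true;
        stack.clear(); comp.clear();
        stack.push_back(i); visited[i] = 1;
        while (!stack.empty()) {
          int c = stack.back(); stack.pop_back();
          comp.push_back(c);
          int cx = c % nx, cy = (c / nx) % ny, cz = c / (nx * ny);
          for (int o = 0; o < 26; ++o) {
            int px = cx + OFF[o][0], py = cy + OFF[o][1], pz = cz + OFF[o][2];
            if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
              continue;
            int p = lin(px, py, pz, nx, ny);
            if (!mask[p]) continue;
            if (vol[p] > v0) is_max = false;
            else if (vol[p] == v0 && !visited[p]) {
              visited[p] = 1;
              stack.push_back(p);
            }
          }
        }
        if (is_max) {
          ++next_label;
          basin_max.push_back(v0);
          for (int c : comp) labels[c] = next_label;
        }
      }

  // pass 2: priority flood from the seeds
  std::priority_queue<QItem, std::vector<QItem>, QCmp> pq;
  long long ord = 0;
  for (int i = 0; i < n; ++i) {
    if (labels[i] == 0) continue;
    int cx = i % nx, cy = (i / nx) % ny, cz = i / (nx * ny);
    for (int o = 0; o < 26; ++o) {
      int px = cx + OFF[o][0], py = cy + OFF[o][1], pz = cz + OFF[o][2];
      if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
        continue;
      int p = lin(px, py, pz, nx, ny);
      if (mask[p] && labels[p] == 0 && !inq[p]) {
        inq[p] = 1;
        pq.push({vol[p], ord++, p});
      }
    }
  }
  while (!pq.empty()) {
    QItem it = pq.top(); pq.pop();
    int i = it.idx;
    if (labels[i] != 0) continue;
    int cx = i % nx, cy = (i / nx) % ny, cz = i / (nx * ny);
    int best = 0;
    double best_max = -1.0;
    for (int o = 0; o < 26; ++o) {
      int px = cx + OFF[o][0], py = cy + OFF[o][1], pz = cz + OFF[o][2];
      if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
        continue;
      int p = lin(px, py, pz, nx, ny);
      int lb = labels[p];
      if (lb > 0) {
        double bm = basin_max[lb - 1];
        if (bm > best_max || (bm == best_max && lb < best)) {
          best_max = bm;
          best = lb;
        }
      } else if (mask[p] && !inq[p]) {
        inq[p] = 1;
        pq.push({vol[p], ord++, p});
      }
    }
    labels[i] = best;   // best > 0: popped voxels always touch a basin
  }
  labels.attr("dim") = dim;
  return labels;
}

// ---------------------------------------------------------------------------
// Grey-level co-occurrence summary over all 26 offsets at distance 1,
// voxel pairs restricted to the target region. Returns
// (contrast, entropy[log2], inverse difference moment, n_pairs).
// ---------------------------------------------------------------------------

// idx: 1-based linear indices of the region's voxels
// [[Rcpp::export]]
NumericVector cpp_glcm_summary(IntegerVector bins, IntegerVector labels,
                               int target, IntegerVector dim,
                               IntegerVector idx) {
  init_offsets();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::map<std::pair<int,int>, double> cc;
  double total = 0.0;
  for (int k = 0; k < idx.size(); ++k) {
    int i = idx[k] - 1;
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    int bi = bins[i];
    for (int o = 0; o < 26; ++o) {
      int px = x + OFF[o][0], py = y + OFF[o][1], pz = z + OFF[o][2];
      if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
        continue;
      int p = lin(px, py, pz, nx, ny);
      if (labels[p] != target) continue;
      cc[{bi, bins[p]}] += 1.0;
      total += 1.0;
    }
  }
  double contrast = 0.0, entropy = 0.0, idm = 0.0;
  if (total > 0) {
    for (auto& kv : cc) {
      double p = kv.second / total;
      double d = kv.first.first - kv.first.second;
      contrast += d * d * p;
      entropy -= p * std::log2(p);
      idm += p / (1.0 + d * d);
    }
  }
  return NumericVector::create(contrast, entropy, idm, total);
}

// ---------------------------------------------------------------------------
// Neighbouring grey-tone difference matrix (Amadasun-King / IBSI), 26-neigh-
// bourhood restricted to the region. Returns per-tone counts n_i and sums
// s_i = sum |i - Abar| over voxels of tone i that have >= 1 valid neighbour.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector bins, IntegerVector labels, int target,
               IntegerVector dim, IntegerVector idx) {
  init_offsets();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::map<int, std::pair<double,double>> m;   // tone -> (n_i, s_i)
  int nvalid = 0;
  for (int k = 0; k < idx.size(); ++k) {
    int i = idx[k] - 1;
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    double nb_sum = 0.0;
    int nb_n = 0;
    for (int o = 0; o < 26; ++o) {
      int px = x + OFF[o][0], py = y + OFF[o][1], pz = z + OFF[o][2];
      if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
        continue;
      int p = lin(px, py, pz, nx, ny);
      if (labels[p] != target) continue;
      nb_sum += bins[p];
      ++nb_n;
    }
    if (nb_n == 0) continue;
    ++nvalid;
    double diff = std::fabs((double)bins[i] - nb_sum / nb_n);
    auto& e = m[bins[i]];
    e.first += 1.0;
    e.second += diff;
  }
  int k = m.size();
  IntegerVector tones(k);
  NumericVector ni(k), si(k);
  int j = 0;
  for (auto& kv : m) {
    tones[j] = kv.first;
    ni[j] = kv.second.first;
    si[j] = kv.second.second;
    ++j;
  }
  return List::create(_["tone"] = tones, _["n"] = ni, _["s"] = si,
                      _["n_valid"] = nvalid);
}

// ---------------------------------------------------------------------------
// Unique pairs of 26-adjacent nonzero labels (a < b).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_adjacent_pairs(IntegerVector labels, IntegerVector dim) {
  init_offsets();
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::set<std::pair<int,int>> pairs;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        int a = labels[i];
        if (a == 0) continue;
        for (int o = 0; o < 26; ++o) {
          int px = x + OFF[o][0], py = y + OFF[o][1], pz = z + OFF[o][2];
          if (px < 0 || px >= nx || py < 0 || py >= ny || pz < 0 || pz >= nz)
            continue;
          int b = labels[lin(px, py, pz, nx, ny)];
          if (b == 0 || b == a) continue;
          pairs.insert({std::min(a, b), std::max(a, b)});
        }
      }
  IntegerMatrix out(pairs.size(), 2);
  int r = 0;
  for (auto& p : pairs) {
    out(r, 0) = p.first;
    out(r, 1) = p.second;
    ++r;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Surface of a region by exposed-face counting (6-connectivity), in mm^2,
// plus the linear indices (1-based) of its surface voxels.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_surface(IntegerVector labels, int target, IntegerVector dim,
                 NumericVector spacing, IntegerVector idx) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double ax = spacing[1] * spacing[2];   // face normal to x
  double ay = spacing[0] * spacing[2];
  double az = spacing[0] * spacing[1];
  const int F[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  const double A[6] = {ax, ax, ay, ay, az, az};
  double area = 0.0;
  std::vector<int> surf;
  for (int k = 0; k < idx.size(); ++k) {
    int i = idx[k] - 1;
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    bool exposed = false;
    for (int f = 0; f < 6; ++f) {
      int px = x + F[f][0], py = y + F[f][1], pz = z + F[f][2];
      bool outside = (px < 0 || px >= nx || py < 0 || py >= ny ||
                      pz < 0 || pz >= nz);
      if (outside || labels[lin(px, py, pz, nx, ny)] != target) {
        area += A[f];
        exposed = true;
      }
    }
    if (exposed) surf.push_back(i + 1);
  }
  return List::create(_["area_mm2"] = area, _["surface_idx"] = wrap(surf));
}
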