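#include <Rcpp.h>
#include <vector>
#include <queue>
#include <algorithm>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Index helpers for column-major 3-D arrays.
static inline int idx3(int i, int j, int k, int nx, int ny) {
  return i + nx * (j + ny * k);
}

// Median of the 26-neighborhood (center excluded). Border voxels use the
// neighbors that exist. Used by the velocity-aliasing detector.
// [[Rcpp::export(name = ".nbhdMedian3d")]]
NumericVector nbhd_median3d(NumericVector vol, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve(26);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        buf.clear();
        for (int dk = -1; dk <= 1; ++dk)
          for (int dj = -1; dj <= 1; ++dj)
            for (int di = -1; di <= 1; ++di) {
              if (di == 0 && dj == 0 && dk == 0) continue;
              int ii = i + di, jj = j + dj, kk = k + dk;
              if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
                continue;
              buf.push_back(vol[idx3(ii, jj, kk, nx, ny)]);
            }
        size_t n = buf.size();
        std::nth_element(buf.begin(), buf.begin() + (n - 1) / 2, buf.end());
        double lo = buf[(n - 1) / 2];
        if (n % 2 == 1) {
          out[idx3(i, j, k, nx, ny)] = lo;
        } else {
          std::nth_element(buf.begin(), buf.begin() + n / 2, buf.end());
          out[idx3(i, j, k, nx, ny)] = 0.5 * (lo + buf[n / 2]);
        }
      }
  return out;
}

// 1-D squared-distance transform (Felzenszwalb & Huttenlocher), helper for
// the exact 3-D Euclidean distance transform below.
static void dt1d(const std::vector<double> &f, std::vector<double> &d) {
  int n = (int)f.size();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * q) - (f[v[k]] + v[k] * v[k])) / (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// Exact Euclidean distance transform of a binary mask: distance (in voxels)
// from each foreground voxel to the nearest background voxel. Voxels outside
// the mask get 0. The grid boundary is NOT treated as background.
// [[Rcpp::export(name = ".edt3d")]]
NumericVector edt3d(LogicalVector mask, IntegerVector dims) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  const double INF = 1e20;
  std::vector<double> g(mask.size());
  for (R_xlen_t t = 0; t < mask.size(); ++t) g[t] = mask[t] ? INF : 0.0;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) f[i] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d);
      for (int i = 0; i < nx; ++i) g[idx3(i, j, k, nx, ny)] = d[i];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d);
      for (int j = 0; j < ny; ++j) g[idx3(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d);
      for (int k = 0; k < nz; ++k) g[idx3(i, j, k, nx, ny)] = d[k];
    }

  NumericVector out(mask.size());
  for (R_xlen_t t = 0; t < mask.size(); ++t)
    out[t] = mask[t] ? std::sqrt(g[t]) : 0.0;
  return out;
}

// Connected-component labeling of a binary mask, 26- or 6-connectivity.
// Labels are 1..n in discovery order; background is 0.
// [[Rcpp::export(name = ".ccLabel3d")]]
IntegerVector cc_label3d(LogicalVector mask, IntegerVector dims,
                         int connectivity = 26) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  IntegerVector lab(mask.size(), 0);
  int next = 0;
  std::queue<int> q;
  for (R_xlen_t s = 0; s < mask.size(); ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    lab[s] = ++next;
    q.push((int)s);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int k = cur / (nx * ny), rem = cur % (nx * ny);
      int j = rem / nx, i = rem % nx;
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0 && dk == 0) continue;
            if (connectivity == 6 && std::abs(di) + std::abs(dj) + std::abs(dk) != 1)
              continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            int t = idx3(ii, jj, kk, nx, ny);
            if (mask[t] && lab[t] == 0) { lab[t] = next; q.push(t); }
          }
    }
  }
  return lab;
}

// Union-find regions of a scalar volume: 6-neighbor voxels are merged when
// their values differ by at most `thr`. Wrap (aliasing) discontinuities
// exceed the threshold and so become region boundaries. Returns compact
// 1-based region labels.
static int uf_find(std::vector<int> &p, int a) {
  while (p[a] != a) { p[a] = p[p[a]]; a = p[a]; }
  return a;
}

// [[Rcpp::export(name = ".wrapRegions")]]
IntegerVector wrap_regions(NumericVector vol, IntegerVector dims, double thr) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int n = nx * ny * nz;
  std::vector<int> p(n);
  for (int i = 0; i < n; ++i) p[i] = i;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        int s = idx3(i, j, k, nx, ny);
        if (i + 1 < nx) {
          int t = s + 1;
          if (std::abs(vol[s] - vol[t]) <= thr)
            p[uf_find(p, s)] = uf_find(p, t);
        }
        if (j + 1 < ny) {
          int t = s + nx;
          if (std::abs(vol[s] - vol[t]) <= thr)
            p[uf_find(p, s)] = uf_find(p, t);
        }
        if (k + 1 < nz) {
          int t = s + nx * ny;
          if (std::abs(vol[s] - vol[t]) <= thr)
            p[uf_find(p, s)] = uf_find(p, t);
        }
      }
  IntegerVector lab(n);
  std::vector<int> remap(n, 0);
  int next = 0;
  for (int i = 0; i < n; ++i) {
    int r = uf_find(p, i);
    if (remap[r] == 0) remap[r] = ++next;
    lab[i] = remap[r];
  }
  return lab;
}
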