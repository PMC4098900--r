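// Low-level 3D grid operations shared by the phantom generator, the GrowCut
// automaton and the feature extractor: exact Euclidean distance transforms
// (Felzenszwalb & Huttenlocher lower-envelope scan, anisotropic spacing),
// separable Gaussian convolution, connected-component labeling and
// Chebyshev (box) dilation.
#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// 1D squared-distance transform of sampled function f at spacing w.
static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0; z[0] = -INF; z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    if (f[q] == INF) continue;
    if (f[v[0]] == INF) { v[0] = q; z[0] = -INF; z[1] = INF; continue; }
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + w2 * q * q) - (f[p] + w2 * p * p)) / (2.0 * w2 * (q - p));
      if (s <= z[k]) { --k; } else break;
    }
    ++k; v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    if (f[v[0]] == INF) { d[q] = INF; continue; }
    while (z[k + 1] < q) ++k;
    double dq = w * (q - v[k]);
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (mm^2) from every voxel to the nearest
// "feature" voxel (mask != 0), honoring per-axis spacing.
// [[Rcpp::export(name = "cpp_edt_sq")]]
NumericVector cpp_edt_sq(LogicalVector mask, IntegerVector dim,
                         NumericVector spacing) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(n);
  for (R_xlen_t i = 0; i < n; ++i) g[i] = mask[i] ? 0.0 : INF;

  std::vector<double> f, d;
  // axis 0 (x, fastest varying)
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
      for (int x = 0; x < nx; ++x) f[x] = g[base + x];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) g[base + x] = d[x];
    }
  // axis 1 (y)
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)z * nx * ny + x;
      for (int y = 0; y < ny; ++y) f[y] = g[base + (R_xlen_t)y * nx];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) g[base + (R_xlen_t)y * nx] = d[y];
    }
  // axis 2 (z)
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      R_xlen_t base = (R_xlen_t)y * nx + x;
      for (int z = 0; z < nz; ++z) f[z] = g[base + (R_xlen_t)z * nx * ny];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) g[base + (R_xlen_t)z * nx * ny] = d[z];
    }
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = g[i];
  out.attr("dim") = dim;
  return out;
}

// Separable convolution along one axis with a symmetric kernel, reflecting
// boundary. kernel has odd length 2r+1.
// [[Rcpp::export(name = "cpp_conv_axis")]]
NumericVector cpp_conv_axis(NumericVector vol, IntegerVector dim,
                            NumericVector kernel, int axis) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const int klen = kernel.size();
  const int r = (klen - 1) / 2;
  NumericVector out(n);
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  R_xlen_t stride; int len;
  if (axis == 0) { stride = sx; len = nx; }
  else if (axis == 1) { stride = sy; len = ny; }
  else { stride = sz; len = nz; }
  // iterate over all lines along `axis`
  for (int z = 0; z < (axis == 2 ? 1 : nz); ++z)
    for (int y = 0; y < (axis == 1 ? 1 : ny); ++y)
      for (int x = 0; x < (axis == 0 ? 1 : nx); ++x) {
        R_xlen_t base = (R_xlen_t)z * sz + (R_xlen_t)y * sy + x;
        for (int i = 0; i < len; ++i) {
          double acc = 0.0;
          for (int j = -r; j <= r; ++j) {
            int idx = i + j;
            if (idx < 0) idx = -idx;                 // reflect
            if (idx >= len) idx = 2 * len - 2 - idx;
            if (idx < 0) idx = 0;                    // len == 1 guard
            acc += kernel[j + r] * vol[base + (R_xlen_t)idx * stride];
          }
          out[base + (R_xlen_t)i * stride] = acc;
        }
      }
  out.attr("dim") = dim;
  return out;
}

// Connected-component labeling (6- or 26-connectivity). Labels are assigned
// in increasing order of the smallest linear index in each component, so
// component 1 always contains the first in-mask voxel in array order.
// [[Rcpp::export(name = "cpp_label_components")]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dim,
                                   int connectivity) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n);
  std::fill(lab.begin(), lab.end(), 0);
  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        int cheb = std::abs(cx) + std::abs(cy) + std::abs(cz);
        if (connectivity == 6 && cheb != 1) continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }
  int next = 0;
  std::queue<R_xlen_t> q;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next; q.push(s);
    while (!q.empty()) {
      R_xlen_t p = q.front(); q.pop();
      int x = (int)(p % nx), y = (int)((p / nx) % ny), z = (int)(p / ((R_xlen_t)nx * ny));
      for (size_t k = 0; k < dx.size(); ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        R_xlen_t pp = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (mask[pp] && lab[pp] == 0) { lab[pp] = next; q.push(pp); }
      }
    }
  }
  lab.attr("dim") = dim;
  return lab;
}

// Chebyshev dilation: repeated 26-neighborhood dilation, `radius` times.
// [[Rcpp::export(name = "cpp_dilate_chebyshev")]]
LogicalVector cpp_dilate_chebyshev(LogicalVector mask, IntegerVector dim,
                                   int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> cur(n), nxt(n);
  for (R_xlen_t i = 0; i < n; ++i) cur[i] = mask[i] ? 1 : 0;
  for (int it = 0; it < radius; ++it) {
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          R_xlen_t p = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x;
          char v = cur[p];
          if (!v) {
            for (int cz = std::max(0, z - 1); !v && cz <= std::min(nz - 1, z + 1); ++cz)
              for (int cy = std::max(0, y - 1); !v && cy <= std::min(ny - 1, y + 1); ++cy)
                for (int cx = std::max(0, x - 1); !v && cx <= std::min(nx - 1, x + 1); ++cx)
                  if (cur[(R_xlen_t)cz * nx * ny + (R_xlen_t)cy * nx + cx]) v = 1;
          }
          nxt[p] = v;
        }
    cur.swap(nxt);
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = cur[i] != 0;
  out.attr("dim") = dim;
  return out;
}
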