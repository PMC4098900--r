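// GrowCut competitive region-growing cellular automaton.
// Each voxel carries a label and a strength in [0,1]; a labeled neighbor q
// attacks voxel p iff g(|C_p - C_q|) * theta_q > theta_p with
// g(x) = 1 - x / max_intensity_difference. Updates are synchronous (computed
// from the previous sweep's state) so a run is a pure function of its seeds.
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export(name = "cpp_growcut")]]
List cpp_growcut(NumericVector vol, IntegerVector dim, IntegerVector seeds,
                 LogicalVector roi, int connectivity, int max_iters) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;

  std::vector<int> dx, dy, dz;
  for (int cz = -1; cz <= 1; ++cz)
    for (int cy = -1; cy <= 1; ++cy)
      for (int cx = -1; cx <= 1; ++cx) {
        if (cx == 0 && cy == 0 && cz == 0) continue;
        if (connectivity == 6 && std::abs(cx) + std::abs(cy) + std::abs(cz) != 1)
          continue;
        dx.push_back(cx); dy.push_back(cy); dz.push_back(cz);
      }

  // fixed similarity scale: intensity range over the ROI
  double cmin = R_PosInf, cmax = R_NegInf;
  for (R_xlen_t i = 0; i < n; ++i)
    if (roi[i]) {
      if (vol[i] < cmin) cmin = vol[i];
      if (vol[i] > cmax) cmax = vol[i];
    }
  double maxdiff = cmax - cmin;
  if (!(maxdiff > 0)) maxdiff = 1.0;  // constant ROI: g == 1 everywhere

  std::vector<int> lab(n), lab2(n);
  std::vector<double> th(n), th2(n);
  std::vector<R_xlen_t> roi_idx;
  for (R_xlen_t i = 0; i < n; ++i) {
    lab[i] = seeds[i];
    th[i] = seeds[i] != 0 ? 1.0 : 0.0;
    if (roi[i]) roi_idx.push_back(i);
  }

  int iter = 0;
  bool converged = false;
  while (iter < max_iters) {
    ++iter;
    bool changed = false;
    lab2 = lab; th2 = th;
    for (size_t ii = 0; ii < roi_idx.size(); ++ii) {
      R_xlen_t p = roi_idx[ii];
      int x = (int)(p % nx), y = (int)((p / nx) % ny),
          z = (int)(p / ((R_xlen_t)nx * ny));
      double best = th[p];
      int bestlab = lab[p];
      for (size_t k = 0; k < dx.size(); ++k) {
        int xx = x + dx[k], yy = y + dy[k], zz = z + dz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
          continue;
        R_xlen_t q = (R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx;
        if (!roi[q] || lab[q] == 0) continue;
        double g = 1.0 - std::fabs(vol[p] - vol[q]) / maxdiff;
        if (g < 0) g = 0;
        double s = g * th[q];
        if (s > best) { best = s; bestlab = lab[q]; }
      }
      if (best > th[p]) {
        if (bestlab != lab[p]) changed = true;
        lab2[p] = bestlab; th2[p] = best;
      }
    }
    lab.swap(lab2); th.swap(th2);
    if (!changed) { converged = true; break; }
  }

  IntegerVector labels(n);
  NumericVector strength(n);
  for (R_xlen_t i = 0; i < n; ++i) { labels[i] = lab[i]; strength[i] = th[i]; }
  labels.attr("dim") = dim;
  strength.attr("dim") = dim;
  return List::create(_["labels"] = labels, _["strength"] = strength,
                      _["iterations"] = iter, _["converged"] = converged);
}
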