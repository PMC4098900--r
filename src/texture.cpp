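// Texture-matrix construction for discretized volumes: gray-level
// co-occurrence (GLCM) and gray-level run-length (GLRLM) counts along a
// single integer displacement direction. Voxels outside the mask carry
// level 0 and never contribute; runs are broken at the mask boundary.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Symmetric co-occurrence counts: each ordered pair (p, p + d*dist) with both
// endpoints in the mask is tallied in both (l1,l2) and (l2,l1).
// [[Rcpp::export(name = "cpp_glcm")]]
NumericMatrix cpp_glcm(IntegerVector levels, IntegerVector dim, int L,
                       IntegerVector direction, int distance) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = direction[0] * distance, oy = direction[1] * distance,
            oz = direction[2] * distance;
  NumericMatrix M(L, L);
  for (int z = 0; z < nz; ++z) {
    int zz = z + oz;
    if (zz < 0 || zz >= nz) continue;
    for (int y = 0; y < ny; ++y) {
      int yy = y + oy;
      if (yy < 0 || yy >= ny) continue;
      for (int x = 0; x < nx; ++x) {
        int xx = x + ox;
        if (xx < 0 || xx >= nx) continue;
        int l1 = levels[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x];
        int l2 = levels[(R_xlen_t)zz * nx * ny + (R_xlen_t)yy * nx + xx];
        if (l1 == 0 || l2 == 0) continue;
        M(l1 - 1, l2 - 1) += 1.0;
        M(l2 - 1, l1 - 1) += 1.0;
      }
    }
  }
  return M;
}

// Maximal-run counts: entry (g, r) = number of maximal in-mask runs of level
// g and length r along `direction`. Each lattice line is traversed once from
// its entry voxel.
// [[Rcpp::export(name = "cpp_glrlm")]]
NumericMatrix cpp_glrlm(IntegerVector levels, IntegerVector dim, int L,
                        IntegerVector direction) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const int ox = direction[0], oy = direction[1], oz = direction[2];
  int rmax = 1;
  if (ox != 0) rmax = nx;
  if (oy != 0 && ny > rmax) rmax = std::max(rmax, ny);
  if (oz != 0 && nz > rmax) rmax = std::max(rmax, nz);
  NumericMatrix M(L, rmax);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        // start of a lattice line: predecessor is off-grid
        int px = x - ox, py = y - oy, pz = z - oz;
        if (px >= 0 && px < nx && py >= 0 && py < ny && pz >= 0 && pz < nz)
          continue;
        int cx = x, cy = y, cz = z;
        int cur = 0, len = 0;
        while (cx >= 0 && cx < nx && cy >= 0 && cy < ny && cz >= 0 && cz < nz) {
          int l = levels[(R_xlen_t)cz * nx * ny + (R_xlen_t)cy * nx + cx];
          if (l == cur) {
            if (l != 0) ++len;
          } else {
            if (cur != 0) M(cur - 1, len - 1) += 1.0;
            cur = l;
            len = (l != 0) ? 1 : 0;
          }
          cx += ox; cy += oy; cz += oz;
        }
        if (cur != 0) M(cur - 1, len - 1) += 1.0;
      }
  return M;
}

// Largest pairwise Euclidean distance between rows of an m x 3 coordinate
// matrix (already in physical units).
// [[Rcpp::export(name = "cpp_max_pairwise_dist")]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  const int m = pts.nrow();
  double best = 0.0;
  for (int i = 0; i < m; ++i)
    for (int j = i + 1; j < m; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
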