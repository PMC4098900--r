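// Iso-surface area by marching tetrahedra: each grid cell is split into six
// tetrahedra around the main diagonal; the iso-level crossing inside a
// tetrahedron is a triangle or a quad with linearly interpolated vertices.
// Physical (mm) coordinates via per-axis spacing.
#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

struct V3 { double x, y, z; };

static inline V3 lerp(const V3& a, const V3& b, double va, double vb, double iso) {
  double t = (iso - va) / (vb - va);
  V3 r;
  r.x = a.x + t * (b.x - a.x);
  r.y = a.y + t * (b.y - a.y);
  r.z = a.z + t * (b.z - a.z);
  return r;
}

static inline double tri_area(const V3& a, const V3& b, const V3& c) {
  double ux = b.x - a.x, uy = b.y - a.y, uz = b.z - a.z;
  double vx = c.x - a.x, vy = c.y - a.y, vz = c.z - a.z;
  double cx = uy * vz - uz * vy;
  double cy = uz * vx - ux * vz;
  double cz = ux * vy - uy * vx;
  return 0.5 * std::sqrt(cx * cx + cy * cy + cz * cz);
}

// area contribution of one tetrahedron
static double tet_area(const V3 p[4], const double v[4], double iso) {
  bool in[4];
  int nin = 0;
  for (int i = 0; i < 4; ++i) { in[i] = v[i] >= iso; if (in[i]) ++nin; }
  if (nin == 0 || nin == 4) return 0.0;
  int a[4], b[4], na = 0, nb = 0;
  for (int i = 0; i < 4; ++i) (in[i] ? a[na++] : b[nb++]) = i;
  if (nin == 1 || nin == 3) {
    int apex = (nin == 1) ? a[0] : b[0];
    int othr[3]; int k = 0;
    for (int i = 0; i < 4; ++i) if (i != apex) othr[k++] = i;
    V3 q0 = lerp(p[apex], p[othr[0]], v[apex], v[othr[0]], iso);
    V3 q1 = lerp(p[apex], p[othr[1]], v[apex], v[othr[1]], iso);
    V3 q2 = lerp(p[apex], p[othr[2]], v[apex], v[othr[2]], iso);
    return tri_area(q0, q1, q2);
  }
  // nin == 2: quad with vertices on the four mixed edges
  V3 q0 = lerp(p[a[0]], p[b[0]], v[a[0]], v[b[0]], iso);
  V3 q1 = lerp(p[a[0]], p[b[1]], v[a[0]], v[b[1]], iso);
  V3 q2 = lerp(p[a[1]], p[b[1]], v[a[1]], v[b[1]], iso);
  V3 q3 = lerp(p[a[1]], p[b[0]], v[a[1]], v[b[0]], iso);
  return tri_area(q0, q1, q2) + tri_area(q0, q2, q3);
}

// [[Rcpp::export(name = "cpp_mesh_area")]]
double cpp_mesh_area(NumericVector field, IntegerVector dim,
                     NumericVector spacing, double iso) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // the six tetrahedra share the cell diagonal (0,0,0)-(1,1,1);
  // cube corner bit code: x + 2y + 4z
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 1, 5, 7}, {0, 2, 3, 7},
    {0, 2, 6, 7}, {0, 4, 5, 7}, {0, 4, 6, 7}
  };
  double area = 0.0;
  for (int z = 0; z + 1 < nz; ++z)
    for (int y = 0; y + 1 < ny; ++y)
      for (int x = 0; x + 1 < nx; ++x) {
        double cv[8];
        V3 cp[8];
        bool anyin = false, anyout = false;
        for (int c = 0; c < 8; ++c) {
          int cx = x + (c & 1), cy = y + ((c >> 1) & 1), cz = z + ((c >> 2) & 1);
          cv[c] = field[(R_xlen_t)cz * nx * ny + (R_xlen_t)cy * nx + cx];
          cp[c].x = cx * sx; cp[c].y = cy * sy; cp[c].z = cz * sz;
          if (cv[c] >= iso) anyin = true; else anyout = true;
        }
        if (!anyin || !anyout) continue;
        for (int t = 0; t < 6; ++t) {
          V3 p[4]; double v[4];
          for (int i = 0; i < 4; ++i) { p[i] = cp[tets[t][i]]; v[i] = cv[tets[t][i]]; }
          area += tet_area(p, v, iso);
        }
      }
  return area;
}
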