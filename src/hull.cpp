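// Discrete convex hull of a set of voxels on an integer grid.
// Voxel coordinates are small integers, so all orientation predicates are
// evaluated exactly in 64-bit integer arithmetic; degenerate seed sets
// (single voxel, collinear, coplanar) are handled by rank reduction.
#include <Rcpp.h>
#include <vector>
#include <set>
#include <utility>
#include <cstdint>
using namespace Rcpp;

struct P3 { int64_t x, y, z; };

static inline P3 sub(const P3& a, const P3& b) {
  P3 r; r.x = a.x - b.x; r.y = a.y - b.y; r.z = a.z - b.z; return r;
}
static inline P3 cross(const P3& a, const P3& b) {
  P3 r;
  r.x = a.y * b.z - a.z * b.y;
  r.y = a.z * b.x - a.x * b.z;
  r.z = a.x * b.y - a.y * b.x;
  return r;
}
static inline int64_t dot(const P3& a, const P3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
// > 0 iff d is on the positive side of plane (a, b, c)
static inline int64_t orient3d(const P3& a, const P3& b, const P3& c, const P3& d) {
  return dot(cross(sub(b, a), sub(c, a)), sub(d, a));
}
static inline int64_t cross2(int64_t ox, int64_t oy, int64_t ax, int64_t ay,
                             int64_t bx, int64_t by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

struct Face { int a, b, c; };

// Incremental convex hull for points of affine rank 3. Returns faces with
// outward orientation (orient3d(face, q) > 0 means q lies strictly outside).
static std::vector<Face> hull3d(const std::vector<P3>& pts,
                                int i0, int i1, int i2, int i3) {
  std::vector<Face> faces;
  int64_t o = orient3d(pts[i0], pts[i1], pts[i2], pts[i3]);
  // orient initial tetrahedron so every face points away from the 4th vertex
  if (o > 0) std::swap(i1, i2);
  faces.push_back({i0, i1, i2});
  faces.push_back({i0, i3, i1});
  faces.push_back({i1, i3, i2});
  faces.push_back({i2, i3, i0});
  const int n = (int)pts.size();
  for (int p = 0; p < n; ++p) {
    if (p == i0 || p == i1 || p == i2 || p == i3) continue;
    std::vector<char> vis(faces.size(), 0);
    bool any = false;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (orient3d(pts[faces[f].a], pts[faces[f].b], pts[faces[f].c], pts[p]) > 0) {
        vis[f] = 1; any = true;
      }
    }
    if (!any) continue;  // inside or on the current hull
    // horizon = directed edges of visible faces whose reverse is not visible
    std::set<std::pair<int,int> > edges;
    for (size_t f = 0; f < faces.size(); ++f) {
      if (!vis[f]) continue;
      int e[3][2] = {{faces[f].a, faces[f].b},
                     {faces[f].b, faces[f].c},
                     {faces[f].c, faces[f].a}};
      for (int k = 0; k < 3; ++k) {
        std::pair<int,int> rev(e[k][1], e[k][0]);
        if (edges.count(rev)) edges.erase(rev);
        else edges.insert(std::make_pair(e[k][0], e[k][1]));
      }
    }
    std::vector<Face> kept;
    for (size_t f = 0; f < faces.size(); ++f)
      if (!vis[f]) kept.push_back(faces[f]);
    for (std::set<std::pair<int,int> >::iterator it = edges.begin();
         it != edges.end(); ++it)
      kept.push_back({it->first, it->second, p});
    faces.swap(kept);
  }
  return faces;
}

// Membership grid of the convex hull of `points` (m x 3 matrix of 0-based
// voxel coordinates) on a grid of dimensions `dim`.
// [[Rcpp::export(name = "cpp_hull_mask")]]
LogicalVector cpp_hull_mask(IntegerMatrix points, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  LogicalVector out(n);
  std::fill(out.begin(), out.end(), FALSE);
  out.attr("dim") = dim;
  const int m = points.nrow();
  if (m == 0) stop("convex hull requires at least one labeled voxel");

  std::vector<P3> pts;
  std::set<std::vector<int64_t> > seen;
  for (int i = 0; i < m; ++i) {
    std::vector<int64_t> key(3);
    key[0] = points(i, 0); key[1] = points(i, 1); key[2] = points(i, 2);
    if (seen.insert(key).second) {
      P3 p; p.x = key[0]; p.y = key[1]; p.z = key[2];
      pts.push_back(p);
    }
  }
  // bounding box restricts the candidate voxels
  int lo[3] = {nx, ny, nz}, hi[3] = {-1, -1, -1};
  for (size_t i = 0; i < pts.size(); ++i) {
    int c[3] = {(int)pts[i].x, (int)pts[i].y, (int)pts[i].z};
    for (int k = 0; k < 3; ++k) {
      if (c[k] < lo[k]) lo[k] = c[k];
      if (c[k] > hi[k]) hi[k] = c[k];
    }
  }
  // determine affine rank via pivots i0..i3
  int i0 = 0, i1 = -1, i2 = -1, i3 = -1;
  for (size_t i = 1; i < pts.size(); ++i)
    if (pts[i].x != pts[i0].x || pts[i].y != pts[i0].y || pts[i].z != pts[i0].z) {
      i1 = (int)i; break;
    }
  if (i1 >= 0) {
    P3 u = sub(pts[i1], pts[i0]);
    for (size_t i = 0; i < pts.size(); ++i) {
      P3 c = cross(u, sub(pts[i], pts[i0]));
      if (c.x != 0 || c.y != 0 || c.z != 0) { i2 = (int)i; break; }
    }
  }
  if (i2 >= 0) {
    for (size_t i = 0; i < pts.size(); ++i)
      if (orient3d(pts[i0], pts[i1], pts[i2], pts[i]) != 0) { i3 = (int)i; break; }
  }

  if (i1 < 0) {                                   // rank 0: single voxel
    R_xlen_t p = (R_xlen_t)pts[0].z * nx * ny + (R_xlen_t)pts[0].y * nx + pts[0].x;
    out[p] = TRUE;
    return out;
  }

  if (i2 < 0) {                                   // rank 1: segment
    P3 u = sub(pts[i1], pts[i0]);
    int64_t tmin = 0, tmax = 0;
    for (size_t i = 0; i < pts.size(); ++i) {
      int64_t t = dot(sub(pts[i], pts[i0]), u);
      if (t < tmin) tmin = t;
      if (t > tmax) tmax = t;
    }
    for (int z = lo[2]; z <= hi[2]; ++z)
      for (int y = lo[1]; y <= hi[1]; ++y)
        for (int x = lo[0]; x <= hi[0]; ++x) {
          P3 q; q.x = x; q.y = y; q.z = z;
          P3 c = cross(sub(q, pts[i0]), u);
          if (c.x != 0 || c.y != 0 || c.z != 0) continue;
          int64_t t = dot(sub(q, pts[i0]), u);
          if (t >= tmin && t <= tmax)
            out[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = TRUE;
        }
    return out;
  }

  if (i3 < 0) {                                   // rank 2: planar polygon
    P3 nrm = cross(sub(pts[i1], pts[i0]), sub(pts[i2], pts[i0]));
    // drop the axis with the largest normal component
    int drop = 0;
    int64_t best = std::llabs(nrm.x);
    if (std::llabs(nrm.y) > best) { best = std::llabs(nrm.y); drop = 1; }
    if (std::llabs(nrm.z) > best) { drop = 2; }
    std::vector<std::pair<int64_t,int64_t> > pp;
    for (size_t i = 0; i < pts.size(); ++i) {
      int64_t c[3] = {pts[i].x, pts[i].y, pts[i].z};
      if (drop == 0) pp.push_back(std::make_pair(c[1], c[2]));
      else if (drop == 1) pp.push_back(std::make_pair(c[0], c[2]));
      else pp.push_back(std::make_pair(c[0], c[1]));
    }
    // Andrew monotone chain on the projected points
    std::sort(pp.begin(), pp.end());
    pp.erase(std::unique(pp.begin(), pp.end()), pp.end());
    std::vector<std::pair<int64_t,int64_t> > h(2 * pp.size());
    int k = 0;
    for (size_t i = 0; i < pp.size(); ++i) {
      while (k >= 2 && cross2(h[k-2].first, h[k-2].second, h[k-1].first,
                              h[k-1].second, pp[i].first, pp[i].second) <= 0) --k;
      h[k++] = pp[i];
    }
    int lower = k + 1;
    for (int i = (int)pp.size() - 2; i >= 0; --i) {
      while (k >= lower && cross2(h[k-2].first, h[k-2].second, h[k-1].first,
                                  h[k-1].second, pp[i].first, pp[i].second) <= 0) --k;
      h[k++] = pp[i];
    }
    h.resize(k > 1 ? k - 1 : k);
    for (int z = lo[2]; z <= hi[2]; ++z)
      for (int y = lo[1]; y <= hi[1]; ++y)
        for (int x = lo[0]; x <= hi[0]; ++x) {
          P3 q; q.x = x; q.y = y; q.z = z;
          if (dot(nrm, sub(q, pts[i0])) != 0) continue;
          int64_t qc[3] = {q.x, q.y, q.z};
          int64_t qx, qy;
          if (drop == 0) { qx = qc[1]; qy = qc[2]; }
          else if (drop == 1) { qx = qc[0]; qy = qc[2]; }
          else { qx = qc[0]; qy = qc[1]; }
          bool inside = true;
          for (size_t e = 0; e < h.size() && inside; ++e) {
            size_t f = (e + 1) % h.size();
            if (h.size() == 1) break;
            if (cross2(h[e].first, h[e].second, h[f].first, h[f].second, qx, qy) < 0)
              inside = false;
          }
          if (h.size() == 1)
            inside = (qx == h[0].first && qy == h[0].second);
          if (inside)
            out[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = TRUE;
        }
    return out;
  }

  std::vector<Face> faces = hull3d(pts, i0, i1, i2, i3);   // rank 3
  for (int z = lo[2]; z <= hi[2]; ++z)
    for (int y = lo[1]; y <= hi[1]; ++y)
      for (int x = lo[0]; x <= hi[0]; ++x) {
        P3 q; q.x = x; q.y = y; q.z = z;
        bool inside = true;
        for (size_t f = 0; f < faces.size() && inside; ++f)
          if (orient3d(pts[faces[f].a], pts[faces[f].b], pts[faces[f].c], q) > 0)
            inside = false;
        if (inside)
          out[(R_xlen_t)z * nx * ny + (R_xlen_t)y * nx + x] = TRUE;
      }
  return out;
}
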