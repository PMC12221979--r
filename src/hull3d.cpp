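#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <map>
#include <utility>

using namespace Rcpp;

// Incremental 3-D convex hull (quickhull-style visibility walk).
// Points are expected in "general enough" position; near-coplanar points
// within tol of a supporting plane are treated as interior, so facet-sampled
// clouds reduce to their corner vertices.

namespace {

struct Vec3 {
  double x, y, z;
};

inline Vec3 sub(const Vec3 &a, const Vec3 &b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
inline Vec3 cross(const Vec3 &a, const Vec3 &b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dot(const Vec3 &a, const Vec3 &b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
inline double norm(const Vec3 &a) { return std::sqrt(dot(a, a)); }

struct Face {
  int a, b, c;       // vertex indices, outward CCW
  Vec3 n;            // unit outward normal
  double off;        // n . x = off on the face plane
  bool alive;
};

Face make_face(int ia, int ib, int ic, const std::vector<Vec3> &P,
               const Vec3 &inner) {
  Face f;
  f.a = ia; f.b = ib; f.c = ic;
  Vec3 nn = cross(sub(P[ib], P[ia]), sub(P[ic], P[ia]));
  double nl = norm(nn);
  if (nl <= 0) nl = 1.0;
  f.n = {nn.x / nl, nn.y / nl, nn.z / nl};
  f.off = dot(f.n, P[ia]);
  if (dot(f.n, inner) > f.off) {  // flip to point away from the interior
    std::swap(f.b, f.c);
    f.n = {-f.n.x, -f.n.y, -f.n.z};
    f.off = -f.off;
  }
  f.alive = true;
  return f;
}

}  // namespace

// [[Rcpp::export(name = ".hull3d_cpp")]]
List hull3d_cpp(NumericMatrix pts, double rel_tol = 1e-9) {
  const int n = pts.nrow();
  if (pts.ncol() != 3) stop("hull error: points must be an N x 3 matrix");
  if (n < 4) stop("hull error: need at least 4 points");
  std::vector<Vec3> P(n);
  double scale = 0.0;
  for (int i = 0; i < n; ++i) {
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    if (!std::isfinite(P[i].x) || !std::isfinite(P[i].y) || !std::isfinite(P[i].z))
      stop("hull error: non-finite coordinate");
    scale = std::max(scale, std::max(std::fabs(P[i].x),
                     std::max(std::fabs(P[i].y), std::fabs(P[i].z))));
  }
  if (scale <= 0) stop("hull error: all points at the origin");
  const double tol = rel_tol * scale;

  // Initial simplex: spread points.
  int i0 = 0, i1 = -1;
  for (int i = 1; i < n; ++i)
    if (P[i].x < P[i0].x || (P[i].x == P[i0].x && P[i].y < P[i0].y)) i0 = i;
  double best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = norm(sub(P[i], P[i0]));
    if (d > best) { best = d; i1 = i; }
  }
  if (best <= tol) stop("hull error: degenerate input (all points coincide)");
  int i2 = -1; best = -1.0;
  Vec3 e01 = sub(P[i1], P[i0]);
  for (int i = 0; i < n; ++i) {
    double d = norm(cross(e01, sub(P[i], P[i0]))) / norm(e01);
    if (d > best) { best = d; i2 = i; }
  }
  if (best <= tol) stop("hull error: degenerate input (collinear points)");
  Vec3 nrm = cross(e01, sub(P[i2], P[i0]));
  double nl = norm(nrm);
  nrm = {nrm.x / nl, nrm.y / nl, nrm.z / nl};
  int i3 = -1; best = -1.0;
  for (int i = 0; i < n; ++i) {
    double d = std::fabs(dot(nrm, sub(P[i], P[i0])));
    if (d > best) { best = d; i3 = i; }
  }
  if (best <= tol) stop("hull error: degenerate input (coplanar points)");

  Vec3 inner = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
                (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
                (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};
  std::vector<Face> faces;
  faces.push_back(make_face(i0, i1, i2, P, inner));
  faces.push_back(make_face(i0, i1, i3, P, inner));
  faces.push_back(make_face(i0, i2, i3, P, inner));
  faces.push_back(make_face(i1, i2, i3, P, inner));

  for (int ip = 0; ip < n; ++ip) {
    if (ip == i0 || ip == i1 || ip == i2 || ip == i3) continue;
    // visible faces
    std::vector<int> vis;
    for (size_t f = 0; f < faces.size(); ++f)
      if (faces[f].alive && dot(faces[f].n, P[ip]) - faces[f].off > tol)
        vis.push_back((int)f);
    if (vis.empty()) continue;
    // horizon: edges of visible faces whose reverse is not in a visible face
    std::map<std::pair<int, int>, int> edge_count;
    for (int fi : vis) {
      const Face &f = faces[fi];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int k = 0; k < 3; ++k) edge_count[{e[k][0], e[k][1]}]++;
    }
    std::vector<std::pair<int, int>> horizon;
    for (auto &kv : edge_count) {
      auto rev = std::make_pair(kv.first.second, kv.first.first);
      if (edge_count.find(rev) == edge_count.end())
        horizon.push_back(kv.first);
    }
    if (horizon.empty()) continue;  // numerically interior after all
    for (int fi : vis) faces[fi].alive = false;
    for (auto &e : horizon)
      faces.push_back(make_face(e.first, e.second, ip, P, inner));
  }

  // collect
  std::vector<int> live;
  for (size_t f = 0; f < faces.size(); ++f)
    if (faces[f].alive) live.push_back((int)f);
  const int m = (int)live.size();
  IntegerMatrix tri(m, 3);
  NumericMatrix normals(m, 3);
  NumericVector offsets(m);
  double area = 0.0, vol6 = 0.0;
  double cx = 0.0, cy = 0.0, cz = 0.0;
  std::vector<bool> used(n, false);
  for (int r = 0; r < m; ++r) {
    const Face &f = faces[live[r]];
    tri(r, 0) = f.a + 1; tri(r, 1) = f.b + 1; tri(r, 2) = f.c + 1;
    normals(r, 0) = f.n.x; normals(r, 1) = f.n.y; normals(r, 2) = f.n.z;
    offsets[r] = f.off;
    used[f.a] = used[f.b] = used[f.c] = true;
    Vec3 A = P[f.a], B = P[f.b], C = P[f.c];
    double a2 = norm(cross(sub(B, A), sub(C, A)));
    area += 0.5 * a2;
    double v6 = dot(A, cross(B, C));  // signed tet (origin, A, B, C) * 6
    vol6 += v6;
    cx += v6 * (A.x + B.x + C.x) / 4.0;
    cy += v6 * (A.y + B.y + C.y) / 4.0;
    cz += v6 * (A.z + B.z + C.z) / 4.0;
  }
  double volume = vol6 / 6.0;
  NumericVector centroid(3);
  if (std::fabs(vol6) > 0) {
    centroid[0] = cx / vol6; centroid[1] = cy / vol6; centroid[2] = cz / vol6;
  }
  std::vector<int> vertex_idx;
  for (int i = 0; i < n; ++i)
    if (used[i]) vertex_idx.push_back(i + 1);
  return List::create(
      _["faces"] = tri, _["normals"] = normals, _["offsets"] = offsets,
      _["area"] = area, _["volume"] = volume, _["centroid"] = centroid,
      _["vertex_indices"] = wrap(vertex_idx));
}
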