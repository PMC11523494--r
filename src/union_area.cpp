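// Exact area of the union of 2D triangles (the mesh footprint on z = 0).
//
// Green's-theorem formulation: orient every projected triangle CCW; the
// union boundary consists of the sub-segments of triangle edges whose left
// side is covered and right side is uncovered. Each edge is split at every
// intersection with edges of other triangles, each sub-segment is
// classified by point-in-triangle coverage tests at slightly offset
// midpoints, and boundary sub-segments accumulate the shoelace integral.
// Coincident boundary sub-segments (e.g. two coplanar sheets projecting to
// the same outline) are de-duplicated so the outline counts once.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <unordered_set>
#include <vector>
using namespace Rcpp;

namespace {

struct Pt { double x, y; };

inline double cross(const Pt& o, const Pt& a, const Pt& b) {
  return (a.x - o.x) * (b.y - o.y) - (a.y - o.y) * (b.x - o.x);
}

// does point p lie in triangle (a,b,c) (CCW), boundary inclusive?
inline bool in_tri(const Pt& p, const Pt& a, const Pt& b, const Pt& c,
                   double eps) {
  return cross(a, b, p) >= -eps && cross(b, c, p) >= -eps &&
         cross(c, a, p) >= -eps;
}

} // namespace

// [[Rcpp::export(name = ".union_area_cpp")]]
double union_area_cpp(NumericMatrix px, NumericMatrix py) {
  const int m = px.nrow(); // triangles, columns are the 3 corners
  if (m == 0) return 0.0;
  std::vector<Pt> A(m), B(m), C(m);
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  std::vector<bool> alive(m, true);
  for (int i = 0; i < m; ++i) {
    Pt a{px(i, 0), py(i, 0)}, b{px(i, 1), py(i, 1)}, c{px(i, 2), py(i, 2)};
    double s = cross(a, b, c);
    if (s < 0) std::swap(b, c); // force CCW
    A[i] = a; B[i] = b; C[i] = c;
    xmin = std::min({xmin, a.x, b.x, c.x}); xmax = std::max({xmax, a.x, b.x, c.x});
    ymin = std::min({ymin, a.y, b.y, c.y}); ymax = std::max({ymax, a.y, b.y, c.y});
  }
  const double diag = std::hypot(xmax - xmin, ymax - ymin);
  if (!(diag > 0)) stop("degenerate projection: all vertices project to a point");
  const double eps = 1e-12 * diag * diag;  // area-scale epsilon
  const double leps = 1e-12 * diag;        // length-scale epsilon
  for (int i = 0; i < m; ++i)
    if (std::fabs(cross(A[i], B[i], C[i])) <= 2 * eps) alive[i] = false;

  // collect directed edges of live triangles with owner ids
  struct Edge { Pt p, q; int owner; };
  std::vector<Edge> edges;
  edges.reserve(3 * (size_t)m);
  for (int i = 0; i < m; ++i) {
    if (!alive[i]) continue;
    edges.push_back({A[i], B[i], i});
    edges.push_back({B[i], C[i], i});
    edges.push_back({C[i], A[i], i});
  }
  const int ne = (int)edges.size();
  if (ne == 0) stop("degenerate projection: all triangles collapse to lines");

  // A directed edge whose exact reverse also occurs belongs to two
  // triangles covering opposite sides: it is interior to the union and can
  // be skipped outright. This prunes nearly every edge of a non-folded
  // projection, leaving outline and fold edges only.
  const double qe = 1e12 / diag;
  auto pkey = [&](const Pt& a, const Pt& b) {
    const long long ax = (long long)std::llround((a.x - xmin) * qe);
    const long long ay = (long long)std::llround((a.y - ymin) * qe);
    const long long bx = (long long)std::llround((b.x - xmin) * qe);
    const long long by = (long long)std::llround((b.y - ymin) * qe);
    // order-sensitive 128-bit-ish hash folded to 64 bits
    unsigned long long h = 1469598103934665603ull;
    for (long long v : {ax, ay, bx, by}) {
      h ^= (unsigned long long)v + 0x9e3779b97f4a7c15ull;
      h *= 1099511628211ull;
    }
    return h;
  };
  std::unordered_set<unsigned long long> dirset;
  dirset.reserve(2 * ne);
  for (const auto& ed : edges) dirset.insert(pkey(ed.p, ed.q));
  std::vector<char> skip(ne, 0);
  for (int e = 0; e < ne; ++e)
    if (dirset.count(pkey(edges[e].q, edges[e].p))) skip[e] = 1;

  const double off = 1e-7 * diag; // offset for side classification

  double area2 = 0.0; // twice the union area
  std::vector<double> ts;
  struct Key { long long x1, y1, x2, y2; };
  std::vector<Key> seen;
  seen.reserve(ne * 2);
  const double qk = 1e11 / diag; // quantisation for de-duplication

  for (int e = 0; e < ne; ++e) {
    if (skip[e]) continue;
    const Pt p = edges[e].p, q = edges[e].q;
    const double ex = q.x - p.x, ey = q.y - p.y;
    const double elen = std::hypot(ex, ey);
    if (elen <= leps) continue;
    ts.clear();
    ts.push_back(0.0); ts.push_back(1.0);
    const double ebx1 = std::min(p.x, q.x) - leps, ebx2 = std::max(p.x, q.x) + leps;
    const double eby1 = std::min(p.y, q.y) - leps, eby2 = std::max(p.y, q.y) + leps;
    for (int e2 = 0; e2 < ne; ++e2) {
      if (e2 == e || edges[e2].owner == edges[e].owner) continue;
      const Pt r = edges[e2].p, s = edges[e2].q;
      if (std::max(r.x, s.x) < ebx1 || std::min(r.x, s.x) > ebx2 ||
          std::max(r.y, s.y) < eby1 || std::min(r.y, s.y) > eby2) continue;
      const double d1 = cross(p, q, r), d2 = cross(p, q, s);
      if (std::fabs(d1) <= eps && std::fabs(d2) <= eps) {
        // collinear: project endpoints onto e
        double t1 = ((r.x - p.x) * ex + (r.y - p.y) * ey) / (elen * elen);
        double t2 = ((s.x - p.x) * ex + (s.y - p.y) * ey) / (elen * elen);
        if (t1 > 0 && t1 < 1) ts.push_back(t1);
        if (t2 > 0 && t2 < 1) ts.push_back(t2);
        continue;
      }
      const double d3 = cross(r, s, p), d4 = cross(r, s, q);
      if ((d1 > eps && d2 > eps) || (d1 < -eps && d2 < -eps) ||
          (d3 > eps && d4 > eps) || (d3 < -eps && d4 < -eps)) continue;
      const double denom = d1 - d2;
      if (std::fabs(denom) <= eps) {
        // an endpoint touches the line of e: split at its projection
        for (const Pt* z : {&r, &s}) {
          double t = ((z->x - p.x) * ex + (z->y - p.y) * ey) / (elen * elen);
          if (t > 0 && t < 1 && std::fabs(cross(p, q, *z)) <= eps)
            ts.push_back(t);
        }
        continue;
      }
      // proper or touching intersection: p + u*(q-p) on the r-s line at
      // u = cross(r,s,p) / (cross(r,s,p) - cross(r,s,q))
      const double u = d3 / (d3 - d4);
      if (u > 0 && u < 1) ts.push_back(u);
    }
    std::sort(ts.begin(), ts.end());
    for (size_t k = 0; k + 1 < ts.size(); ++k) {
      const double t0 = ts[k], t1 = ts[k + 1];
      if (t1 - t0 <= 1e-14) continue;
      const double tm = 0.5 * (t0 + t1);
      const Pt mid{p.x + tm * ex, p.y + tm * ey};
      // left normal of the (CCW) directed edge
      const double nx = -ey / elen, ny = ex / elen;
      const Pt right{mid.x - off * nx, mid.y - off * ny};
      // the owner covers the left side by construction; boundary iff the
      // right side is covered by nothing
      bool covered = false;
      for (int i = 0; i < m && !covered; ++i) {
        if (!alive[i]) continue;
        if (in_tri(right, A[i], B[i], C[i], eps)) covered = true;
      }
      if (covered) continue;
      const Pt s0{p.x + t0 * ex, p.y + t0 * ey};
      const Pt s1{p.x + t1 * ex, p.y + t1 * ey};
      Key key{(long long)std::llround((s0.x - xmin) * qk),
              (long long)std::llround((s0.y - ymin) * qk),
              (long long)std::llround((s1.x - xmin) * qk),
              (long long)std::llround((s1.y - ymin) * qk)};
      bool dup = false;
      for (const Key& kk : seen)
        if (kk.x1 == key.x1 && kk.y1 == key.y1 && kk.x2 == key.x2 &&
            kk.y2 == key.y2) { dup = true; break; }
      if (dup) continue;
      seen.push_back(key);
      area2 += s0.x * s1.y - s1.x * s0.y;
    }
  }
  return 0.5 * std::fabs(area2);
}
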