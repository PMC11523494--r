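// Ambient-occlusion visibility (PCV) ray casting.
//
// For every vertex and every sky direction d with d . n(vertex) > 0, a ray
// from the vertex (offset a small distance along its normal to avoid
// self-hits) is tested against the whole mesh; the vertex's PCV is the
// fraction of directions that escape. A median-split AABB BVH over the
// faces gives any-hit queries in O(log F); Moller-Trumbore is used for the
// ray-triangle test. Fully deterministic: no RNG anywhere.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct Vec { double x, y, z; };
inline Vec operator-(const Vec& a, const Vec& b) { return {a.x - b.x, a.y - b.y, a.z - b.z}; }
inline Vec crossv(const Vec& a, const Vec& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
inline double dotv(const Vec& a, const Vec& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }

struct Tri { Vec a, e1, e2; };

struct Node {
  double bmin[3], bmax[3];
  int left, right;   // children, or -1
  int start, count;  // leaf: face range in the index array
};

struct BVH {
  std::vector<Tri> tris;
  std::vector<Vec> centroids;
  std::vector<int> idx;
  std::vector<Node> nodes;

  void node_bounds(Node& n) {
    for (int k = 0; k < 3; ++k) { n.bmin[k] = R_PosInf; n.bmax[k] = R_NegInf; }
    for (int i = n.start; i < n.start + n.count; ++i) {
      const Tri& t = tris[idx[i]];
      const Vec b = {t.a.x + t.e1.x, t.a.y + t.e1.y, t.a.z + t.e1.z};
      const Vec c = {t.a.x + t.e2.x, t.a.y + t.e2.y, t.a.z + t.e2.z};
      const Vec* ps[3] = {&t.a, &b, &c};
      for (const Vec* p : ps) {
        n.bmin[0] = std::min(n.bmin[0], p->x); n.bmax[0] = std::max(n.bmax[0], p->x);
        n.bmin[1] = std::min(n.bmin[1], p->y); n.bmax[1] = std::max(n.bmax[1], p->y);
        n.bmin[2] = std::min(n.bmin[2], p->z); n.bmax[2] = std::max(n.bmax[2], p->z);
      }
    }
  }

  int build(int start, int count) {
    Node n; n.start = start; n.count = count; n.left = n.right = -1;
    node_bounds(n);
    int me = (int)nodes.size();
    nodes.push_back(n);
    if (count <= 4) return me;
    int ax = 0;
    double ext[3] = {n.bmax[0] - n.bmin[0], n.bmax[1] - n.bmin[1], n.bmax[2] - n.bmin[2]};
    if (ext[1] > ext[ax]) ax = 1;
    if (ext[2] > ext[ax]) ax = 2;
    auto cen = [&](int f) { const Vec& c = centroids[f];
      return ax == 0 ? c.x : (ax == 1 ? c.y : c.z); };
    std::nth_element(idx.begin() + start, idx.begin() + start + count / 2,
                     idx.begin() + start + count,
                     [&](int p, int q) { return cen(p) < cen(q); });
    int l = build(start, count / 2);
    int r = build(start + count / 2, count - count / 2);
    nodes[me].left = l; nodes[me].right = r;
    nodes[me].count = 0;
    return me;
  }

  bool any_hit(const Vec& o, const Vec& d) const {
    double inv[3] = {1.0 / d.x, 1.0 / d.y, 1.0 / d.z};
    int stack[128];
    int top = 0;
    stack[top++] = 0;
    while (top > 0) {
      const Node& n = nodes[stack[--top]];
      // slab test
      double tmin = 0.0, tmax = R_PosInf;
      const double od[3] = {o.x, o.y, o.z};
      bool miss = false;
      for (int k = 0; k < 3; ++k) {
        double t1 = (n.bmin[k] - od[k]) * inv[k];
        double t2 = (n.bmax[k] - od[k]) * inv[k];
        if (t1 > t2) std::swap(t1, t2);
        tmin = std::max(tmin, t1); tmax = std::min(tmax, t2);
        if (tmin > tmax) { miss = true; break; }
      }
      if (miss) continue;
      if (n.left < 0) {
        for (int i = n.start; i < n.start + n.count; ++i) {
          const Tri& t = tris[idx[i]];
          const Vec pv = crossv(d, t.e2);
          const double det = dotv(t.e1, pv);
          if (std::fabs(det) < 1e-300) continue;
          const double invdet = 1.0 / det;
          const Vec tv = o - t.a;
          const double u = dotv(tv, pv) * invdet;
          if (u < 0.0 || u > 1.0) continue;
          const Vec qv = crossv(tv, t.e1);
          const double v = dotv(d, qv) * invdet;
          if (v < 0.0 || u + v > 1.0) continue;
          const double th = dotv(t.e2, qv) * invdet;
          if (th > 0.0) return true;
        }
      } else if (top < 126) {
        stack[top++] = n.left;
        stack[top++] = n.right;
      }
    }
    return false;
  }
};

} // namespace

// dirs: k x 3 unit directions; verts/normals: n x 3; faces: m x 3 (1-based)
// offset: ray-origin offset along the vertex normal.
// Returns per-vertex counts of unoccluded directions among those with
// d . n > 0, plus the number of candidate directions per vertex.
// [[Rcpp::export(name = ".pcv_cpp")]]
List pcv_cpp(NumericMatrix verts, IntegerMatrix faces, NumericMatrix normals,
             NumericMatrix dirs, double offset) {
  const int nv = verts.nrow(), nf = faces.nrow(), nd = dirs.nrow();
  BVH bvh;
  bvh.tris.resize(nf);
  bvh.centroids.resize(nf);
  bvh.idx.resize(nf);
  for (int i = 0; i < nf; ++i) {
    const int i1 = faces(i, 0) - 1, i2 = faces(i, 1) - 1, i3 = faces(i, 2) - 1;
    Vec a{verts(i1, 0), verts(i1, 1), verts(i1, 2)};
    Vec b{verts(i2, 0), verts(i2, 1), verts(i2, 2)};
    Vec c{verts(i3, 0), verts(i3, 1), verts(i3, 2)};
    bvh.tris[i] = {a, b - a, c - a};
    bvh.centroids[i] = {(a.x + b.x + c.x) / 3, (a.y + b.y + c.y) / 3,
                        (a.z + b.z + c.z) / 3};
    bvh.idx[i] = i;
  }
  bvh.nodes.reserve(2 * nf);
  bvh.build(0, nf);

  IntegerVector seen(nv), cand(nv);
  for (int v = 0; v < nv; ++v) {
    const Vec n{normals(v, 0), normals(v, 1), normals(v, 2)};
    const Vec o{verts(v, 0) + offset * n.x, verts(v, 1) + offset * n.y,
                verts(v, 2) + offset * n.z};
    int s = 0, c = 0;
    for (int k = 0; k < nd; ++k) {
      const Vec d{dirs(k, 0), dirs(k, 1), dirs(k, 2)};
      if (dotv(d, n) <= 0.0) continue;
      ++c;
      if (!bvh.any_hit(o, d)) ++s;
    }
    seen[v] = s; cand[v] = c;
  }
  return List::create(_["seen"] = seen, _["candidates"] = cand);
}
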