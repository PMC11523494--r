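// Quadric edge-collapse decimation (Garland-Heckbert).
//
// Each vertex accumulates the area-weighted plane quadrics of its incident
// faces; boundary edges add perpendicular constraint planes so open-surface
// crops keep their outline. Edges are collapsed cheapest-first (lazy-deleted
// binary heap) to the position minimising the summed quadric, with a
// normal-preservation guard (no incident face may flip or collapse) and a
// link-condition guard against non-manifold pinching. Collapsing stops once
// the face count reaches the target; blocked edges are skipped, so the
// achieved count can sit slightly above the target on pathological input.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <queue>
#include <set>
#include <vector>
using namespace Rcpp;

namespace {

struct Quadric {
  // symmetric 4x4: a2 ab ac ad; b2 bc bd; c2 cd; d2
  double q[10] = {0,0,0,0,0,0,0,0,0,0};
  void add_plane(double a, double b, double c, double d, double w) {
    q[0] += w*a*a; q[1] += w*a*b; q[2] += w*a*c; q[3] += w*a*d;
    q[4] += w*b*b; q[5] += w*b*c; q[6] += w*b*d;
    q[7] += w*c*c; q[8] += w*c*d; q[9] += w*d*d;
  }
  void add(const Quadric& o) { for (int i = 0; i < 10; ++i) q[i] += o.q[i]; }
  double eval(double x, double y, double z) const {
    return q[0]*x*x + 2*q[1]*x*y + 2*q[2]*x*z + 2*q[3]*x
         + q[4]*y*y + 2*q[5]*y*z + 2*q[6]*y
         + q[7]*z*z + 2*q[8]*z + q[9];
  }
  // solve for the minimiser; false if near-singular
  bool optimum(double& x, double& y, double& z) const {
    const double a11 = q[0], a12 = q[1], a13 = q[2];
    const double a22 = q[4], a23 = q[5], a33 = q[7];
    const double det = a11*(a22*a33 - a23*a23) - a12*(a12*a33 - a23*a13)
                     + a13*(a12*a23 - a22*a13);
    const double scale = std::max({std::fabs(a11), std::fabs(a22), std::fabs(a33), 1e-300});
    if (std::fabs(det) < 1e-9 * scale * scale * scale) return false;
    const double b1 = -q[3], b2 = -q[6], b3 = -q[8];
    x = (b1*(a22*a33 - a23*a23) - a12*(b2*a33 - a23*b3) + a13*(b2*a23 - a22*b3)) / det;
    y = (a11*(b2*a33 - a23*b3) - b1*(a12*a33 - a23*a13) + a13*(a12*b3 - b2*a13)) / det;
    z = (a11*(a22*b3 - b2*a23) - a12*(a12*b3 - b2*a13) + b1*(a12*a23 - a22*a13)) / det;
    return true;
  }
};

struct V3 { double x, y, z; };
inline V3 sub(const V3& a, const V3& b) { return {a.x-b.x, a.y-b.y, a.z-b.z}; }
inline V3 crossv(const V3& a, const V3& b) {
  return {a.y*b.z - a.z*b.y, a.z*b.x - a.x*b.z, a.x*b.y - a.y*b.x};
}
inline double dotv(const V3& a, const V3& b) { return a.x*b.x + a.y*b.y + a.z*b.z; }
inline double norm(const V3& a) { return std::sqrt(dotv(a, a)); }

struct HeapItem {
  double cost; int v1, v2; unsigned long stamp;
  bool operator<(const HeapItem& o) const { return cost > o.cost; } // min-heap
};

} // namespace

// [[Rcpp::export(name = ".decimate_cpp")]]
List decimate_cpp(NumericMatrix verts, IntegerMatrix faces, int target) {
  const int nv = verts.nrow();
  const int nf = faces.nrow();
  std::vector<V3> P(nv);
  for (int i = 0; i < nv; ++i) P[i] = {verts(i,0), verts(i,1), verts(i,2)};
  std::vector<std::array<int,3>> F(nf);
  for (int i = 0; i < nf; ++i) F[i] = {faces(i,0)-1, faces(i,1)-1, faces(i,2)-1};

  std::vector<bool> fdead(nf, false), vdead(nv, false);
  std::vector<std::vector<int>> vf(nv); // incident faces (lazily pruned)
  for (int i = 0; i < nf; ++i)
    for (int k = 0; k < 3; ++k) vf[F[i][k]].push_back(i);

  // vertex quadrics from face planes (area weight)
  std::vector<Quadric> Q(nv);
  auto face_plane = [&](int fi, double& a, double& b, double& c, double& d,
                        double& area) {
    const V3& p0 = P[F[fi][0]]; const V3& p1 = P[F[fi][1]]; const V3& p2 = P[F[fi][2]];
    V3 nrm = crossv(sub(p1, p0), sub(p2, p0));
    const double len = norm(nrm);
    area = 0.5 * len;
    if (len < 1e-300) { a = b = c = d = 0; return; }
    a = nrm.x/len; b = nrm.y/len; c = nrm.z/len;
    d = -(a*p0.x + b*p0.y + c*p0.z);
  };
  double total_area = 0;
  for (int i = 0; i < nf; ++i) {
    double a,b,c,d,ar; face_plane(i, a, b, c, d, ar);
    total_area += ar;
    for (int k = 0; k < 3; ++k) Q[F[i][k]].add_plane(a, b, c, d, ar / 3.0);
  }

  // boundary constraint planes: perpendicular to the face through the edge
  {
    std::vector<std::pair<long long,int>> ecount;
    ecount.reserve(3 * (size_t)nf);
    auto ekey = [&](int u, int v) {
      if (u > v) std::swap(u, v);
      return (long long)u * nv + v;
    };
    for (int i = 0; i < nf; ++i)
      for (int k = 0; k < 3; ++k)
        ecount.push_back({ekey(F[i][k], F[i][(k+1)%3]), i});
    std::sort(ecount.begin(), ecount.end());
    const double bw = 100.0 * total_area / std::max(nf, 1); // strong weight
    for (size_t i = 0; i < ecount.size(); ) {
      size_t j = i;
      while (j < ecount.size() && ecount[j].first == ecount[i].first) ++j;
      if (j - i == 1) {
        const int fi = ecount[i].second;
        const int u = (int)(ecount[i].first / nv), v = (int)(ecount[i].first % nv);
        double a,b,c,d,ar; face_plane(fi, a, b, c, d, ar);
        V3 e = sub(P[v], P[u]);
        V3 pn = crossv(e, {a, b, c}); // perpendicular to face, contains edge
        const double len = norm(pn);
        if (len > 1e-300) {
          pn = {pn.x/len, pn.y/len, pn.z/len};
          const double pd = -dotv(pn, P[u]);
          Q[u].add_plane(pn.x, pn.y, pn.z, pd, bw);
          Q[v].add_plane(pn.x, pn.y, pn.z, pd, bw);
        }
      }
      i = j;
    }
  }

  std::vector<unsigned long> vstamp(nv, 0);
  std::priority_queue<HeapItem> heap;

  auto neighbours = [&](int v, std::vector<int>& out) {
    out.clear();
    for (int fi : vf[v]) {
      if (fdead[fi]) continue;
      for (int k = 0; k < 3; ++k)
        if (F[fi][k] != v) out.push_back(F[fi][k]);
    }
    std::sort(out.begin(), out.end());
    out.erase(std::unique(out.begin(), out.end()), out.end());
  };

  auto edge_cost = [&](int v1, int v2, V3& pos) {
    Quadric qq = Q[v1]; qq.add(Q[v2]);
    double x, y, z;
    if (!qq.optimum(x, y, z)) {
      // fallback: best of the endpoints and midpoint
      const V3 cand[3] = {P[v1], P[v2],
                          {(P[v1].x+P[v2].x)/2, (P[v1].y+P[v2].y)/2, (P[v1].z+P[v2].z)/2}};
      double best = R_PosInf;
      for (const V3& c : cand) {
        const double e = qq.eval(c.x, c.y, c.z);
        if (e < best) { best = e; pos = c; }
      }
      return best;
    }
    pos = {x, y, z};
    return qq.eval(x, y, z);
  };

  std::vector<int> nb;
  for (int v = 0; v < nv; ++v) {
    if (vf[v].empty()) continue;
    neighbours(v, nb);
    for (int u : nb) if (u > v) {
      V3 pos;
      heap.push({edge_cost(v, u, pos), v, u, vstamp[v] + vstamp[u]});
    }
  }

  int faces_alive = nf;
  std::vector<int> nb1, nb2, shared;
  while (faces_alive > target && !heap.empty()) {
    HeapItem it = heap.top(); heap.pop();
    const int v1 = it.v1, v2 = it.v2;
    if (vdead[v1] || vdead[v2]) continue;
    if (it.stamp != vstamp[v1] + vstamp[v2]) continue; // stale
    // still an edge?
    bool isedge = false;
    for (int fi : vf[v1]) {
      if (fdead[fi]) continue;
      for (int k = 0; k < 3; ++k) if (F[fi][k] == v2) { isedge = true; break; }
      if (isedge) break;
    }
    if (!isedge) continue;

    // link condition: common neighbours must be exactly the opposite
    // vertices of the shared faces
    neighbours(v1, nb1); neighbours(v2, nb2);
    shared.clear();
    std::set_intersection(nb1.begin(), nb1.end(), nb2.begin(), nb2.end(),
                          std::back_inserter(shared));
    int shared_faces = 0;
    for (int fi : vf[v1]) {
      if (fdead[fi]) continue;
      bool has2 = false;
      for (int k = 0; k < 3; ++k) if (F[fi][k] == v2) has2 = true;
      if (has2) ++shared_faces;
    }
    if ((int)shared.size() != shared_faces) continue;

    V3 pos;
    edge_cost(v1, v2, pos);

    // normal-preservation guard: no surviving incident face may flip
    bool ok = true;
    for (int pass = 0; pass < 2 && ok; ++pass) {
      const int vv = pass == 0 ? v1 : v2;
      for (int fi : vf[vv]) {
        if (fdead[fi]) continue;
        bool dies = false;
        for (int k = 0; k < 3; ++k)
          if (F[fi][k] == (pass == 0 ? v2 : v1)) dies = true;
        if (dies) continue;
        V3 p[3], pnew[3];
        for (int k = 0; k < 3; ++k) {
          p[k] = P[F[fi][k]];
          pnew[k] = (F[fi][k] == vv) ? pos : P[F[fi][k]];
        }
        V3 n0 = crossv(sub(p[1], p[0]), sub(p[2], p[0]));
        V3 n1 = crossv(sub(pnew[1], pnew[0]), sub(pnew[2], pnew[0]));
        if (dotv(n0, n1) <= 1e-12 * dotv(n0, n0)) { ok = false; break; }
      }
    }
    if (!ok) continue;

    // collapse v2 -> v1 at pos
    P[v1] = pos;
    Q[v1].add(Q[v2]);
    for (int fi : vf[v2]) {
      if (fdead[fi]) continue;
      bool has1 = false;
      for (int k = 0; k < 3; ++k) if (F[fi][k] == v1) has1 = true;
      if (has1) { fdead[fi] = true; --faces_alive; }
      else {
        for (int k = 0; k < 3; ++k) if (F[fi][k] == v2) F[fi][k] = v1;
        vf[v1].push_back(fi);
      }
    }
    vdead[v2] = true;
    ++vstamp[v2];
    // re-rank edges around the new vertex
    ++vstamp[v1];
    neighbours(v1, nb);
    for (int u : nb) {
      V3 dum;
      heap.push({edge_cost(v1, u, dum), v1, u, vstamp[v1] + vstamp[u]});
    }
  }

  // compact
  std::vector<int> remap(nv, -1);
  int nvo = 0;
  for (int i = 0; i < nf; ++i) {
    if (fdead[i]) continue;
    for (int k = 0; k < 3; ++k)
      if (remap[F[i][k]] < 0) remap[F[i][k]] = nvo++;
  }
  NumericMatrix vo(nvo, 3);
  for (int v = 0; v < nv; ++v)
    if (remap[v] >= 0) {
      vo(remap[v], 0) = P[v].x; vo(remap[v], 1) = P[v].y; vo(remap[v], 2) = P[v].z;
    }
  int nfo = 0;
  for (int i = 0; i < nf; ++i) if (!fdead[i]) ++nfo;
  IntegerMatrix fo(nfo, 3);
  int r = 0;
  for (int i = 0; i < nf; ++i) {
    if (fdead[i]) continue;
    for (int k = 0; k < 3; ++k) fo(r, k) = remap[F[i][k]] + 1;
    ++r;
  }
  return List::create(_["vertices"] = vo, _["faces"] = fo,
                      _["achieved"] = nfo);
}
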