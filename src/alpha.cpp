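// 2D Delaunay triangulation (Bowyer-Watson) and alpha-complex area, used by
// the alpha-shape mode of the projected occlusal area. The alpha complex
// keeps the Delaunay triangles whose circumradius is at most alpha; its
// area is the sum of kept triangle areas. A tiny deterministic symbolic
// jitter breaks the exact cocircularity of grid-sampled vertices.

#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cmath>
#include <vector>
using namespace Rcpp;

namespace {

struct DTri { int a, b, c; bool dead; };

inline double orient2(double ax, double ay, double bx, double by,
                      double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// > 0 when p lies inside the circumcircle of CCW triangle (a, b, c)
inline double incircle(double ax, double ay, double bx, double by,
                       double cx, double cy, double px, double py) {
  const double adx = ax - px, ady = ay - py;
  const double bdx = bx - px, bdy = by - py;
  const double cdx = cx - px, cdy = cy - py;
  const double ad = adx * adx + ady * ady;
  const double bd = bdx * bdx + bdy * bdy;
  const double cd = cdx * cdx + cdy * cdy;
  return adx * (bdy * cd - bd * cdy) - ady * (bdx * cd - bd * cdx) +
         ad * (bdx * cdy - bdy * cdx);
}

} // namespace

// Returns the Delaunay triangles (m x 3, 1-based) of the given points.
// [[Rcpp::export(name = ".delaunay_cpp")]]
IntegerMatrix delaunay_cpp(NumericVector x, NumericVector y) {
  const int n = x.size();
  if (n < 3) stop("need at least 3 points for a triangulation");
  double xmin = R_PosInf, xmax = R_NegInf, ymin = R_PosInf, ymax = R_NegInf;
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, x[i]); xmax = std::max(xmax, x[i]);
    ymin = std::min(ymin, y[i]); ymax = std::max(ymax, y[i]);
  }
  const double diag = std::hypot(xmax - xmin, ymax - ymin);
  if (!(diag > 0)) stop("degenerate projection: coincident points");
  std::vector<double> px(n + 3), py(n + 3);
  // deterministic jitter breaks cocircular grids without moving area
  for (int i = 0; i < n; ++i) {
    unsigned h = (unsigned)(i + 1) * 2654435761u;
    const double j1 = ((h & 0xffffu) / 65535.0 - 0.5);
    const double j2 = (((h >> 16) & 0xffffu) / 65535.0 - 0.5);
    px[i] = x[i] + 1e-9 * diag * j1;
    py[i] = y[i] + 1e-9 * diag * j2;
  }
  // super-triangle
  const double cx = 0.5 * (xmin + xmax), cy = 0.5 * (ymin + ymax);
  const double R = 10.0 * diag;
  px[n] = cx - 2 * R; py[n] = cy - R;
  px[n + 1] = cx + 2 * R; py[n + 1] = cy - R;
  px[n + 2] = cx; py[n + 2] = cy + 2 * R;

  std::vector<DTri> tris;
  tris.push_back({n, n + 1, n + 2, false});

  std::vector<int> bad;
  for (int p = 0; p < n; ++p) {
    bad.clear();
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (tris[t].dead) continue;
      const DTri& T = tris[t];
      if (incircle(px[T.a], py[T.a], px[T.b], py[T.b], px[T.c], py[T.c],
                   px[p], py[p]) > 0)
        bad.push_back(t);
    }
    // boundary of the cavity: edges of bad triangles not shared by two bad ones
    std::vector<std::pair<int,int>> poly;
    for (int t : bad) {
      const DTri& T = tris[t];
      const int ed[3][2] = {{T.a, T.b}, {T.b, T.c}, {T.c, T.a}};
      for (auto& e : ed) {
        bool shared = false;
        for (int t2 : bad) {
          if (t2 == t) continue;
          const DTri& U = tris[t2];
          const int f[3][2] = {{U.a, U.b}, {U.b, U.c}, {U.c, U.a}};
          for (auto& g : f)
            if ((g[0] == e[0] && g[1] == e[1]) || (g[0] == e[1] && g[1] == e[0]))
              { shared = true; break; }
          if (shared) break;
        }
        if (!shared) poly.push_back({e[0], e[1]});
      }
    }
    for (int t : bad) tris[t].dead = true;
    for (auto& e : poly) {
      DTri nt{e.first, e.second, p, false};
      if (orient2(px[nt.a], py[nt.a], px[nt.b], py[nt.b], px[nt.c], py[nt.c]) < 0)
        std::swap(nt.b, nt.c);
      tris.push_back(nt);
    }
  }
  std::vector<std::array<int,3>> keep;
  for (const DTri& T : tris) {
    if (T.dead || T.a >= n || T.b >= n || T.c >= n) continue;
    keep.push_back({T.a + 1, T.b + 1, T.c + 1});
  }
  IntegerMatrix out((int)keep.size(), 3);
  for (int i = 0; i < (int)keep.size(); ++i)
    for (int k = 0; k < 3; ++k) out(i, k) = keep[i][k];
  return out;
}
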