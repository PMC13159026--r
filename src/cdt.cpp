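// Constrained Delaunay triangulation of a polygon interior.
//
// Bowyer-Watson incremental Delaunay over a prepared point set (densified
// boundary loop + interior lattice points), followed by constrained-edge
// recovery via edge flips and centroid-in-polygon classification.  The R
// wrapper normalizes coordinates to the unit box, so fixed absolute
// tolerances are adequate here.

#include <Rcpp.h>
#include <vector>
#include <map>
#include <utility>
#include <cmath>
#include <cstdlib>
using namespace Rcpp;

namespace {

struct Tri {
  int a, b, c;
  bool alive;
};

inline double orient2d(double ax, double ay, double bx, double by,
                       double cx, double cy) {
  return (bx - ax) * (cy - ay) - (by - ay) * (cx - ax);
}

// strict incircle test for d against circumcircle of CCW triangle (a,b,c)
inline bool incircle(const std::vector<double>& px, const std::vector<double>& py,
                     int a, int b, int c, int d) {
  const double adx = px[a] - px[d], ady = py[a] - py[d];
  const double bdx = px[b] - px[d], bdy = py[b] - py[d];
  const double cdx = px[c] - px[d], cdy = py[c] - py[d];
  const double ad2 = adx * adx + ady * ady;
  const double bd2 = bdx * bdx + bdy * bdy;
  const double cd2 = cdx * cdx + cdy * cdy;
  const double det = adx * (bdy * cd2 - cdy * bd2)
                   - ady * (bdx * cd2 - cdx * bd2)
                   + ad2 * (bdx * cdy - cdx * bdy);
  return det > 1e-13;
}

inline bool seg_properly_intersect(double ax, double ay, double bx, double by,
                                   double cx, double cy, double dx, double dy) {
  const double o1 = orient2d(ax, ay, bx, by, cx, cy);
  const double o2 = orient2d(ax, ay, bx, by, dx, dy);
  const double o3 = orient2d(cx, cy, dx, dy, ax, ay);
  const double o4 = orient2d(cx, cy, dx, dy, bx, by);
  return ((o1 > 0 && o2 < 0) || (o1 < 0 && o2 > 0)) &&
         ((o3 > 0 && o4 < 0) || (o3 < 0 && o4 > 0));
}

inline long long ekey(int u, int v) {
  if (u > v) std::swap(u, v);
  return (long long)u * 10000000LL + v;
}

bool point_in_poly(double x, double y, const std::vector<double>& bx,
                   const std::vector<double>& by) {
  const int n = (int)bx.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (((by[i] > y) != (by[j] > y)) &&
        (x < (bx[j] - bx[i]) * (y - by[i]) / (by[j] - by[i]) + bx[i]))
      inside = !inside;
  }
  return inside;
}

}  // namespace

// points: n x 2, first n_boundary rows form the closed constraint loop (in
// order).  Returns 1-based CCW triangle indices of the polygon interior.
// [[Rcpp::export(name = ".cdt_triangulate")]]
IntegerMatrix cdt_triangulate(NumericMatrix points, int n_boundary) {
  const int n = points.nrow();
  if (n_boundary < 3 || n < 3) stop("need at least 3 boundary points");
  std::vector<double> px(n + 3), py(n + 3);
  for (int i = 0; i < n; ++i) { px[i] = points(i, 0); py[i] = points(i, 1); }

  // super-triangle far outside the (normalized, ~unit-box) data
  const int s0 = n, s1 = n + 1, s2 = n + 2;
  px[s0] = -50.0; py[s0] = -50.0;
  px[s1] = 50.0;  py[s1] = -50.0;
  px[s2] = 0.0;   py[s2] = 100.0;

  std::vector<Tri> tris;
  tris.push_back({s0, s1, s2, true});

  // deterministic pseudo-shuffled insertion order
  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;
  unsigned int st = 123456789u;
  for (int i = n - 1; i > 0; --i) {
    st ^= st << 13; st ^= st >> 17; st ^= st << 5;
    int j = (int)(st % (unsigned int)(i + 1));
    std::swap(order[i], order[j]);
  }

  std::vector<int> bad;
  for (int oi = 0; oi < n; ++oi) {
    const int p = order[oi];
    bad.clear();
    for (int t = 0; t < (int)tris.size(); ++t) {
      if (!tris[t].alive) continue;
      if (incircle(px, py, tris[t].a, tris[t].b, tris[t].c, p)) bad.push_back(t);
    }
    if (bad.empty()) {
      // tolerance knocked the point out of every circumcircle (degenerate
      // tie); fall back to containing triangle
      for (int t = 0; t < (int)tris.size(); ++t) {
        if (!tris[t].alive) continue;
        const Tri& T = tris[t];
        double o1 = orient2d(px[T.a], py[T.a], px[T.b], py[T.b], px[p], py[p]);
        double o2 = orient2d(px[T.b], py[T.b], px[T.c], py[T.c], px[p], py[p]);
        double o3 = orient2d(px[T.c], py[T.c], px[T.a], py[T.a], px[p], py[p]);
        if (o1 >= -1e-13 && o2 >= -1e-13 && o3 >= -1e-13) { bad.push_back(t); break; }
      }
      if (bad.empty()) stop("point insertion failed (no cavity found)");
    }
    // cavity boundary = edges used exactly once among bad triangles
    std::map<long long, std::pair<int, int> > once;
    for (int bi : bad) {
      const Tri& T = tris[bi];
      const int e[3][2] = {{T.a, T.b}, {T.b, T.c}, {T.c, T.a}};
      for (int k = 0; k < 3; ++k) {
        long long key = ekey(e[k][0], e[k][1]);
        std::map<long long, std::pair<int, int> >::iterator it = once.find(key);
        if (it == once.end()) once[key] = std::make_pair(e[k][0], e[k][1]);
        else once.erase(it);
      }
      tris[bi].alive = false;
    }
    for (std::map<long long, std::pair<int, int> >::iterator it = once.begin();
         it != once.end(); ++it) {
      int u = it->second.first, v = it->second.second;
      double o = orient2d(px[u], py[u], px[v], py[v], px[p], py[p]);
      if (o < 0) std::swap(u, v);
      tris.push_back({u, v, p, true});
    }
  }

  // drop super-triangle incident faces
  for (Tri& T : tris)
    if (T.alive && (T.a >= n || T.b >= n || T.c >= n)) T.alive = false;

  // constrained-edge recovery by flipping crossing edges
  for (int ci = 0; ci < n_boundary; ++ci) {
    const int a = ci, b = (ci + 1) % n_boundary;
    for (int guard = 0; guard < 1000; ++guard) {
      bool present = false;
      for (const Tri& T : tris) {
        if (!T.alive) continue;
        if ((T.a == a || T.b == a || T.c == a) &&
            (T.a == b || T.b == b || T.c == b)) { present = true; break; }
      }
      if (present) break;
      // find an edge properly crossing segment a-b, shared by two triangles
      int t1 = -1, t2 = -1, c = -1, d = -1;
      for (int t = 0; t < (int)tris.size() && t1 < 0; ++t) {
        if (!tris[t].alive) continue;
        const Tri& T = tris[t];
        const int e[3][2] = {{T.a, T.b}, {T.b, T.c}, {T.c, T.a}};
        for (int k = 0; k < 3; ++k) {
          const int u = e[k][0], v = e[k][1];
          if (u == a || u == b || v == a || v == b) continue;
          if (!seg_properly_intersect(px[a], py[a], px[b], py[b],
                                      px[u], py[u], px[v], py[v])) continue;
          // locate the neighbor sharing (u,v)
          for (int t2i = 0; t2i < (int)tris.size(); ++t2i) {
            if (t2i == t || !tris[t2i].alive) continue;
            const Tri& S = tris[t2i];
            if ((S.a == u || S.b == u || S.c == u) &&
                (S.a == v || S.b == v || S.c == v)) {
              t1 = t; t2 = t2i; c = u; d = v; break;
            }
          }
          if (t1 >= 0) break;
        }
      }
      if (t1 < 0) stop("constrained edge recovery failed");
      const Tri& T1 = tris[t1];
      const Tri& T2 = tris[t2];
      const int e1 = T1.a + T1.b + T1.c - c - d;
      const int f1 = T2.a + T2.b + T2.c - c - d;
      // flip c-d -> e1-f1 (only valid if quad convex; if not, a later pass
      // over another crossing edge will unblock it)
      if (!seg_properly_intersect(px[e1], py[e1], px[f1], py[f1],
                                  px[c], py[c], px[d], py[d]))
        stop("constrained edge recovery hit a non-convex quad");
      tris[t1].alive = false;
      tris[t2].alive = false;
      int na = e1, nb = c, nc = f1;
      if (orient2d(px[na], py[na], px[nb], py[nb], px[nc], py[nc]) < 0)
        std::swap(nb, nc);
      tris.push_back({na, nb, nc, true});
      na = e1; nb = d; nc = f1;
      if (orient2d(px[na], py[na], px[nb], py[nb], px[nc], py[nc]) < 0)
        std::swap(nb, nc);
      tris.push_back({na, nb, nc, true});
    }
  }

  // keep triangles whose centroid lies inside the constraint polygon
  std::vector<double> bx(n_boundary), by(n_boundary);
  for (int i = 0; i < n_boundary; ++i) { bx[i] = px[i]; by[i] = py[i]; }
  std::vector<int> keep;
  for (int t = 0; t < (int)tris.size(); ++t) {
    if (!tris[t].alive) continue;
    const Tri& T = tris[t];
    const double cx = (px[T.a] + px[T.b] + px[T.c]) / 3.0;
    const double cy = (py[T.a] + py[T.b] + py[T.c]) / 3.0;
    if (point_in_poly(cx, cy, bx, by)) keep.push_back(t);
  }

  IntegerMatrix out((int)keep.size(), 3);
  for (int i = 0; i < (int)keep.size(); ++i) {
    Tri T = tris[keep[i]];
    if (orient2d(px[T.a], py[T.a], px[T.b], py[T.b], px[T.c], py[T.c]) < 0)
      std::swap(T.b, T.c);
    out(i, 0) = T.a + 1;
    out(i, 1) = T.b + 1;
    out(i, 2) = T.c + 1;
  }
  return out;
}

// simplicity check for a closed polygon: no two non-adjacent edges may
// properly intersect
// [[Rcpp::export(name = ".polygon_is_simple")]]
bool polygon_is_simple(NumericMatrix poly) {
  const int n = poly.nrow();
  for (int i = 0; i < n; ++i) {
    const int i2 = (i + 1) % n;
    for (int j = i + 2; j < n; ++j) {
      const int j2 = (j + 1) % n;
      if (j2 == i) continue;  // adjacent around the wrap
      if (seg_properly_intersect(poly(i, 0), poly(i, 1), poly(i2, 0), poly(i2, 1),
                                 poly(j, 0), poly(j, 1), poly(j2, 0), poly(j2, 1)))
        return false;
    }
  }
  return true;
}

// minimum distance from each query point to a closed polygon boundary
// [[Rcpp::export(name = ".dist_to_polygon")]]
NumericVector dist_to_polygon(NumericMatrix query, NumericMatrix poly) {
  const int nq = query.nrow(), np = poly.nrow();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1);
    double best = R_PosInf;
    for (int j = 0, k = np - 1; j < np; k = j++) {
      const double ax = poly(k, 0), ay = poly(k, 1);
      const double bx = poly(j, 0), by = poly(j, 1);
      const double dx = bx - ax, dy = by - ay;
      const double len2 = dx * dx + dy * dy;
      double t = len2 > 0 ? ((qx - ax) * dx + (qy - ay) * dy) / len2 : 0.0;
      if (t < 0) t = 0; else if (t > 1) t = 1;
      const double ex = ax + t * dx - qx, ey = ay + t * dy - qy;
      const double d = std::sqrt(ex * ex + ey * ey);
      if (d < best) best = d;
    }
    out[i] = best;
  }
  return out;
}

// point-in-polygon for a batch of query points
// [[Rcpp::export(name = ".points_in_polygon")]]
LogicalVector points_in_polygon(NumericMatrix query, NumericMatrix poly) {
  const int nq = query.nrow(), np = poly.nrow();
  std::vector<double> bx(np), by(np);
  for (int i = 0; i < np; ++i) { bx[i] = poly(i, 0); by[i] = poly(i, 1); }
  LogicalVector out(nq);
  for (int i = 0; i < nq; ++i)
    out[i] = point_in_poly(query(i, 0), query(i, 1), bx, by);
  return out;
}
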