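// Alpha-complex persistent homology of a 3-D point cloud.
//
// Pipeline: incremental Bowyer-Watson Delaunay triangulation -> alpha
// filtration values (squared circumradii with the Gabriel correction,
// processed top-down) -> GF(2) boundary-matrix reduction in filtration
// order, with optional representative cycles. Diagrams are returned in
// radius (Angstrom) units. Degenerate (cospherical) configurations are
// expected to be broken by a tiny jitter applied on the R side.

#include <Rcpp.h>
#include <array>
#include <map>
#include <vector>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

typedef std::array<double, 3> P3;

static inline double d2(const P3& a, const P3& b) {
  double s = 0;
  for (int k = 0; k < 3; ++k) { double d = a[k] - b[k]; s += d * d; }
  return s;
}

// circumsphere of 4 points; returns false when degenerate
static bool circumsphere(const P3& a, const P3& b, const P3& c, const P3& d,
                         P3& ctr, double& r2) {
  double M[3][3], rhs[3];
  const P3* pts[3] = { &b, &c, &d };
  for (int i = 0; i < 3; ++i) {
    double nn = 0;
    for (int k = 0; k < 3; ++k) {
      M[i][k] = 2.0 * ((*pts[i])[k] - a[k]);
      nn += ((*pts[i])[k] - a[k]) * ((*pts[i])[k] - a[k]);
    }
    rhs[i] = nn;
  }
  double det =
    M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
    M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
    M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
  double rn = 1.0;   // product of row norms: scale-aware degeneracy test
  for (int i = 0; i < 3; ++i) {
    double s = 0;
    for (int k = 0; k < 3; ++k) s += M[i][k] * M[i][k];
    rn *= std::sqrt(s);
  }
  if (std::fabs(det) < 1e-12 * rn + 1e-300) return false;
  double x[3];
  for (int i = 0; i < 3; ++i) {
    double Mi[3][3];
    for (int r = 0; r < 3; ++r)
      for (int k = 0; k < 3; ++k) Mi[r][k] = (k == i) ? rhs[r] : M[r][k];
    double deti =
      Mi[0][0] * (Mi[1][1] * Mi[2][2] - Mi[1][2] * Mi[2][1]) -
      Mi[0][1] * (Mi[1][0] * Mi[2][2] - Mi[1][2] * Mi[2][0]) +
      Mi[0][2] * (Mi[1][0] * Mi[2][1] - Mi[1][1] * Mi[2][0]);
    x[i] = deti / det;
  }
  r2 = 0;
  for (int k = 0; k < 3; ++k) { ctr[k] = a[k] + x[k]; r2 += x[k] * x[k]; }
  return true;
}

// circumcircle (in-plane circumsphere) of a triangle
static bool circumcircle(const P3& a, const P3& b, const P3& c,
                         P3& ctr, double& r2) {
  P3 u, v;
  for (int k = 0; k < 3; ++k) { u[k] = b[k] - a[k]; v[k] = c[k] - a[k]; }
  double uu = 0, vv = 0, uv = 0;
  for (int k = 0; k < 3; ++k) { uu += u[k] * u[k]; vv += v[k] * v[k]; uv += u[k] * v[k]; }
  double det = uu * vv - uv * uv;
  if (det < 1e-14 * uu * vv + 1e-300) return false;
  double s = (0.5 * uu * vv - 0.5 * vv * uv) / det;
  double t = (0.5 * vv * uu - 0.5 * uu * uv) / det;
  r2 = 0;
  for (int k = 0; k < 3; ++k) {
    double w = s * u[k] + t * v[k];
    ctr[k] = a[k] + w;
    r2 += w * w;
  }
  return true;
}

struct Tet {
  int v[4];
  P3 ctr;
  double r2;
  bool alive;
};

// Bowyer-Watson; returns tetrahedra as vertex index quadruples
static std::vector<std::array<int, 4> > delaunay3d(const std::vector<P3>& pts) {
  int n = (int)pts.size();
  P3 lo = pts[0], hi = pts[0];
  for (const P3& p : pts)
    for (int k = 0; k < 3; ++k) {
      lo[k] = std::min(lo[k], p[k]); hi[k] = std::max(hi[k], p[k]);
    }
  double ext = 1e-9;
  P3 mid;
  for (int k = 0; k < 3; ++k) {
    ext = std::max(ext, hi[k] - lo[k]);
    mid[k] = 0.5 * (lo[k] + hi[k]);
  }
  double big = 1e4 * ext;
  std::vector<P3> P = pts;
  P.push_back({mid[0] - big, mid[1] - big, mid[2] - big});
  P.push_back({mid[0] + big, mid[1], mid[2]});
  P.push_back({mid[0], mid[1] + big, mid[2]});
  P.push_back({mid[0], mid[1], mid[2] + big});
  std::vector<Tet> tets;
  {
    Tet t0;
    t0.v[0] = n; t0.v[1] = n + 1; t0.v[2] = n + 2; t0.v[3] = n + 3;
    if (!circumsphere(P[n], P[n + 1], P[n + 2], P[n + 3], t0.ctr, t0.r2))
      stop("internal: degenerate super-tetrahedron");
    t0.alive = true;
    tets.push_back(t0);
  }
  typedef std::array<int, 3> Face;
  for (int ip = 0; ip < n; ++ip) {
    const P3& p = P[ip];
    std::map<Face, int> faceCount;
    std::vector<int> bad;
    for (int it = 0; it < (int)tets.size(); ++it) {
      if (!tets[it].alive) continue;
      if (d2(p, tets[it].ctr) <= tets[it].r2 * (1.0 + 1e-12)) bad.push_back(it);
    }
    if (bad.empty()) stop("internal: point outside all circumspheres");
    for (int it : bad) {
      tets[it].alive = false;
      static const int fidx[4][3] = { {1,2,3}, {0,2,3}, {0,1,3}, {0,1,2} };
      for (int f = 0; f < 4; ++f) {
        Face fc = { tets[it].v[fidx[f][0]], tets[it].v[fidx[f][1]],
                    tets[it].v[fidx[f][2]] };
        std::sort(fc.begin(), fc.end());
        faceCount[fc]++;
      }
    }
    for (std::map<Face, int>::const_iterator it = faceCount.begin();
         it != faceCount.end(); ++it) {
      if (it->second != 1) continue;     // interior cavity face
      Tet t;
      t.v[0] = it->first[0]; t.v[1] = it->first[1];
      t.v[2] = it->first[2]; t.v[3] = ip;
      if (!circumsphere(P[t.v[0]], P[t.v[1]], P[t.v[2]], P[t.v[3]],
                        t.ctr, t.r2)) {
        stop("degenerate point configuration in Delaunay step; "
             "jitter the input points");
      }
      t.alive = true;
      tets.push_back(t);
    }
  }
  std::vector<std::array<int, 4> > out;
  for (const Tet& t : tets) {
    if (!t.alive) continue;
    if (t.v[0] >= n || t.v[1] >= n || t.v[2] >= n || t.v[3] >= n) continue;
    std::array<int, 4> q = { t.v[0], t.v[1], t.v[2], t.v[3] };
    std::sort(q.begin(), q.end());
    out.push_back(q);
  }
  return out;
}

struct Simplex {
  int dim;
  double alpha2;       // squared filtration radius
  std::array<int, 4> v;  // vertex ids, -1 padded
};

// [[Rcpp::export]]
List cpp_alpha_persistence(NumericMatrix coords, bool with_cycles,
                           double min_persistence) {
  int n = coords.nrow();
  std::vector<P3> pts(n);
  for (int i = 0; i < n; ++i)
    for (int k = 0; k < 3; ++k) pts[i][k] = coords(i, k);

  std::vector<std::array<int, 4> > tets;
  if (n >= 5) {
    tets = delaunay3d(pts);
  } else if (n == 4) {
    // single (possibly degenerate) tetrahedron: full complex
    P3 c; double r2;
    if (circumsphere(pts[0], pts[1], pts[2], pts[3], c, r2))
      tets.push_back({0, 1, 2, 3});
  }
  typedef std::array<int, 3> Tri;
  typedef std::array<int, 2> Edge;
  std::map<Tri, std::vector<int> > triCof;   // triangle -> incident tet ids
  std::map<Edge, std::vector<int> > edgeCof; // edge -> incident tri ids
  std::vector<double> tetAlpha(tets.size());
  std::vector<P3> tetCtr(tets.size());
  for (size_t it = 0; it < tets.size(); ++it) {
    P3 c; double r2;
    circumsphere(pts[tets[it][0]], pts[tets[it][1]], pts[tets[it][2]],
                 pts[tets[it][3]], c, r2);
    tetAlpha[it] = r2;
    tetCtr[it] = c;
    static const int fidx[4][3] = { {1,2,3}, {0,2,3}, {0,1,3}, {0,1,2} };
    for (int f = 0; f < 4; ++f) {
      Tri t = { tets[it][fidx[f][0]], tets[it][fidx[f][1]],
                tets[it][fidx[f][2]] };
      std::sort(t.begin(), t.end());
      triCof[t].push_back((int)it);
    }
  }
  if (n == 3) {   // lone triangle, no tetrahedra
    Tri t = {0, 1, 2};
    triCof[t];    // creates entry with no cofaces
  }
  // triangle alpha values (Gabriel-corrected)
  std::vector<Tri> tris;
  std::vector<double> triAlpha;
  std::vector<P3> triCtr;
  for (std::map<Tri, std::vector<int> >::const_iterator it = triCof.begin();
       it != triCof.end(); ++it) {
    const Tri& t = it->first;
    P3 c; double r2;
    bool ok = circumcircle(pts[t[0]], pts[t[1]], pts[t[2]], c, r2);
    double a2;
    if (!ok) {
      a2 = R_PosInf;
    } else {
      bool gabriel = true;
      for (int ti : it->second) {
        for (int k = 0; k < 4; ++k) {
          int w = tets[ti][k];
          if (w == t[0] || w == t[1] || w == t[2]) continue;
          if (d2(pts[w], c) < r2 * (1.0 - 1e-12)) gabriel = false;
        }
      }
      a2 = r2;
      if (!gabriel) {
        a2 = R_PosInf;
        for (int ti : it->second) a2 = std::min(a2, tetAlpha[ti]);
      }
    }
    tris.push_back(t);
    triAlpha.push_back(a2);
    triCtr.push_back(c);
    static const int eidx[3][2] = { {0,1}, {0,2}, {1,2} };
    for (int e = 0; e < 3; ++e) {
      Edge ed = { t[eidx[e][0]], t[eidx[e][1]] };
      edgeCof[ed].push_back((int)tris.size() - 1);
    }
  }
  if (n == 2) { Edge e = {0, 1}; edgeCof[e]; }
  // edge alpha values
  std::vector<Edge> edges;
  std::vector<double> edgeAlpha;
  for (std::map<Edge, std::vector<int> >::const_iterator it = edgeCof.begin();
       it != edgeCof.end(); ++it) {
    const Edge& e = it->first;
    P3 mid;
    for (int k = 0; k < 3; ++k) mid[k] = 0.5 * (pts[e[0]][k] + pts[e[1]][k]);
    double r2 = 0.25 * d2(pts[e[0]], pts[e[1]]);
    bool gabriel = true;
    for (int ti : it->second) {
      for (int k = 0; k < 3; ++k) {
        int w = tris[ti][k];
        if (w == e[0] || w == e[1]) continue;
        if (d2(pts[w], mid) < r2 * (1.0 - 1e-12)) gabriel = false;
      }
    }
    double a2 = r2;
    if (!gabriel) {
      a2 = R_PosInf;
      for (int ti : it->second) a2 = std::min(a2, triAlpha[ti]);
    }
    edges.push_back(e);
    edgeAlpha.push_back(a2);
  }
  // assemble filtration
  std::vector<Simplex> simp;
  simp.reserve(n + edges.size() + tris.size() + tets.size());
  for (int i = 0; i < n; ++i)
    simp.push_back({0, 0.0, {i, -1, -1, -1}});
  for (size_t i = 0; i < edges.size(); ++i)
    simp.push_back({1, edgeAlpha[i], {edges[i][0], edges[i][1], -1, -1}});
  for (size_t i = 0; i < tris.size(); ++i)
    simp.push_back({2, triAlpha[i], {tris[i][0], tris[i][1], tris[i][2], -1}});
  for (size_t i = 0; i < tets.size(); ++i)
    simp.push_back({3, tetAlpha[i],
                    {tets[i][0], tets[i][1], tets[i][2], tets[i][3]}});
  std::vector<int> order(simp.size());
  for (size_t i = 0; i < order.size(); ++i) order[i] = (int)i;
  std::sort(order.begin(), order.end(), [&](int a, int b) {
    if (simp[a].alpha2 != simp[b].alpha2) return simp[a].alpha2 < simp[b].alpha2;
    return simp[a].dim < simp[b].dim;
  });
  std::vector<int> pos(simp.size());
  for (size_t i = 0; i < order.size(); ++i) pos[order[i]] = (int)i;
  // face lookup: map sorted vertex tuple -> filtration position
  std::map<std::array<int, 4>, int> lookup;
  for (size_t i = 0; i < simp.size(); ++i) lookup[simp[i].v] = pos[i];
  // boundary columns in filtration order
  int m = (int)simp.size();
  std::vector<std::vector<int> > cols(m);
  for (int j = 0; j < m; ++j) {
    const Simplex& s = simp[order[j]];
    if (s.dim == 0) continue;
    std::vector<int> bd;
    for (int drop = 0; drop <= s.dim; ++drop) {
      std::array<int, 4> f = {-1, -1, -1, -1};
      int w = 0;
      for (int k = 0; k <= s.dim; ++k) if (k != drop) f[w++] = s.v[k];
      bd.push_back(lookup[f]);
    }
    std::sort(bd.begin(), bd.end());
    cols[j] = bd;
  }
  // standard reduction
  std::vector<int> lowOf(m, -1);   // low index -> column
  std::vector<std::pair<int, int> > pairs;
  for (int j = 0; j < m; ++j) {
    std::vector<int>& col = cols[j];
    while (!col.empty()) {
      int low = col.back();
      int other = lowOf[low];
      if (other < 0) break;
      // symmetric difference with cols[other]
      std::vector<int> merged;
      std::set_symmetric_difference(col.begin(), col.end(),
                                    cols[other].begin(), cols[other].end(),
                                    std::back_inserter(merged));
      col.swap(merged);
    }
    if (!col.empty()) {
      lowOf[col.back()] = j;
      pairs.push_back(std::make_pair(col.back(), j));
    }
  }
  // collect finite pairs for H1 (edge-triangle) and H2 (triangle-tet)
  List out;
  for (int dim = 1; dim <= 2; ++dim) {
    std::vector<double> birth, death;
    List cyc, bsimp;
    for (size_t p = 0; p < pairs.size(); ++p) {
      int bi = pairs[p].first, dj = pairs[p].second;
      const Simplex& sb = simp[order[bi]];
      const Simplex& sd = simp[order[dj]];
      if (sb.dim != dim || sd.dim != dim + 1) continue;
      if (!R_FINITE(sb.alpha2) || !R_FINITE(sd.alpha2)) continue;
      double b = std::sqrt(std::max(sb.alpha2, 0.0));
      double d = std::sqrt(std::max(sd.alpha2, 0.0));
      if (d - b <= min_persistence) continue;
      birth.push_back(b);
      death.push_back(d);
      {
        std::vector<int> bv;
        for (int k = 0; k <= sb.dim; ++k) bv.push_back(sb.v[k]);
        bsimp.push_back(IntegerVector(bv.begin(), bv.end()));
      }
      if (with_cycles) {
        // reduced column of the death simplex is a representative cycle
        std::vector<int> verts;
        for (int rowpos : cols[dj]) {
          const Simplex& rs = simp[order[rowpos]];
          for (int k = 0; k <= rs.dim; ++k) verts.push_back(rs.v[k]);
        }
        std::sort(verts.begin(), verts.end());
        verts.erase(std::unique(verts.begin(), verts.end()), verts.end());
        cyc.push_back(IntegerVector(verts.begin(), verts.end()));
      }
    }
    List dg = List::create(_["birth"] = NumericVector(birth.begin(), birth.end()),
                           _["death"] = NumericVector(death.begin(), death.end()),
                           _["cycles"] = cyc,
                           _["birth_simplex"] = bsimp);
    out.push_back(dg);
  }
  out.names() = CharacterVector::create("dim1", "dim2");
  return out;
}
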