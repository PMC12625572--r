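#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

// Incremental 3D convex hull. The boundary of a Delaunay tetrahedralization
// of a point set is its convex hull, so this provides the boundary surface
// used for mesh export. Returns 1-based triangle indices, outward oriented.

struct Face {
  int a, b, c;
  double nx, ny, nz, off; // outward normal and plane offset
  bool alive;
};

static void face_plane(const std::vector<double>& px,
                       const std::vector<double>& py,
                       const std::vector<double>& pz,
                       Face& f) {
  double ux = px[f.b] - px[f.a], uy = py[f.b] - py[f.a], uz = pz[f.b] - pz[f.a];
  double vx = px[f.c] - px[f.a], vy = py[f.c] - py[f.a], vz = pz[f.c] - pz[f.a];
  f.nx = uy * vz - uz * vy;
  f.ny = uz * vx - ux * vz;
  f.nz = ux * vy - uy * vx;
  f.off = f.nx * px[f.a] + f.ny * py[f.a] + f.nz * pz[f.a];
}

// [[Rcpp::export]]
IntegerMatrix convex_hull_cpp(NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) stop("at least 4 points are required");
  std::vector<double> px(n), py(n), pz(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    px[i] = pts(i, 0); py[i] = pts(i, 1); pz[i] = pts(i, 2);
    for (int d = 0; d < 3; ++d) {
      double v = pts(i, d);
      if (v < lo[d]) lo[d] = v;
      if (v > hi[d]) hi[d] = v;
    }
  }
  double diag = std::sqrt((hi[0]-lo[0])*(hi[0]-lo[0]) +
                          (hi[1]-lo[1])*(hi[1]-lo[1]) +
                          (hi[2]-lo[2])*(hi[2]-lo[2]));
  if (diag <= 0) stop("degenerate point set (all points coincide)");
  const double eps = 1e-10 * diag * diag; // plane-excess tolerance (area*dist)

  // initial simplex: furthest pair from point 0, then furthest from the
  // line, then furthest from the plane
  int i0 = 0, i1 = 0;
  double best = -1.0;
  for (int i = 1; i < n; ++i) {
    double d2 = (px[i]-px[0])*(px[i]-px[0]) + (py[i]-py[0])*(py[i]-py[0]) +
                (pz[i]-pz[0])*(pz[i]-pz[0]);
    if (d2 > best) { best = d2; i1 = i; }
  }
  if (best <= eps * eps) stop("degenerate point set (all points coincide)");
  best = -1.0;
  int i2 = -1;
  for (int i = 0; i < n; ++i) {
    if (i == i0 || i == i1) continue;
    double ux = px[i1]-px[i0], uy = py[i1]-py[i0], uz = pz[i1]-pz[i0];
    double wx = px[i]-px[i0],  wy = py[i]-py[i0],  wz = pz[i]-pz[i0];
    double cx = uy*wz - uz*wy, cy = uz*wx - ux*wz, cz = ux*wy - uy*wx;
    double a2 = cx*cx + cy*cy + cz*cz;
    if (a2 > best) { best = a2; i2 = i; }
  }
  if (i2 < 0 || best <= eps * eps) stop("degenerate point set (collinear)");
  Face f0 = {i0, i1, i2, 0, 0, 0, 0, true};
  face_plane(px, py, pz, f0);
  best = 0.0;
  int i3 = -1;
  for (int i = 0; i < n; ++i) {
    double ex = std::fabs(f0.nx*px[i] + f0.ny*py[i] + f0.nz*pz[i] - f0.off);
    if (ex > best) { best = ex; i3 = i; }
  }
  if (i3 < 0 || best <= eps) stop("degenerate point set (coplanar)");

  std::vector<Face> faces;
  {
    // orient the four faces of the initial tetrahedron outward
    int tet[4][3] = {{i0,i1,i2},{i0,i1,i3},{i0,i2,i3},{i1,i2,i3}};
    int opp[4] = {i3, i2, i1, i0};
    for (int t = 0; t < 4; ++t) {
      Face f = {tet[t][0], tet[t][1], tet[t][2], 0, 0, 0, 0, true};
      face_plane(px, py, pz, f);
      double ex = f.nx*px[opp[t]] + f.ny*py[opp[t]] + f.nz*pz[opp[t]] - f.off;
      if (ex > 0) { std::swap(f.b, f.c); face_plane(px, py, pz, f); }
      faces.push_back(f);
    }
  }

  std::vector<char> used(n, 0);
  used[i0] = used[i1] = used[i2] = used[i3] = 1;
  for (int p = 0; p < n; ++p) {
    if (used[p]) continue;
    // strictly visible faces first; if any, also absorb coplanar faces
    // (|excess| within tolerance) so coplanar hull vertices are kept and
    // flat patches are retriangulated through the new point
    double maxex = R_NegInf;
    std::vector<int> alive_idx;
    std::vector<double> exs;
    for (size_t t = 0; t < faces.size(); ++t) {
      if (!faces[t].alive) continue;
      double ex = faces[t].nx*px[p] + faces[t].ny*py[p] + faces[t].nz*pz[p] -
                  faces[t].off;
      alive_idx.push_back((int)t);
      exs.push_back(ex);
      if (ex > maxex) maxex = ex;
    }
    if (maxex <= eps) continue;
    std::vector<int> visible;
    for (size_t q = 0; q < alive_idx.size(); ++q) {
      if (exs[q] > -eps) visible.push_back(alive_idx[q]);
    }
    // horizon: directed edges of visible faces whose reverse is not visible
    std::map<std::pair<int,int>, int> edges;
    for (int vi : visible) {
      const Face& f = faces[vi];
      int e[3][2] = {{f.a, f.b}, {f.b, f.c}, {f.c, f.a}};
      for (int q = 0; q < 3; ++q) edges[std::make_pair(e[q][0], e[q][1])]++;
      faces[vi].alive = false;
    }
    for (std::map<std::pair<int,int>, int>::iterator it = edges.begin();
         it != edges.end(); ++it) {
      std::pair<int,int> rev(it->first.second, it->first.first);
      if (edges.count(rev)) continue; // interior edge of the visible patch
      Face f = {it->first.first, it->first.second, p, 0, 0, 0, 0, true};
      face_plane(px, py, pz, f);
      faces.push_back(f);
    }
  }

  int nf = 0;
  for (size_t t = 0; t < faces.size(); ++t) if (faces[t].alive) ++nf;
  IntegerMatrix out(nf, 3);
  int r = 0;
  for (size_t t = 0; t < faces.size(); ++t) {
    if (!faces[t].alive) continue;
    out(r, 0) = faces[t].a + 1;
    out(r, 1) = faces[t].b + 1;
    out(r, 2) = faces[t].c + 1;
    ++r;
  }
  return out;
}
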