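#include "morph.h"
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

// cube corner offsets, corner c -> (x,y,z) in {0,1}
const int CX[8] = {0, 1, 1, 0, 0, 1, 1, 0};
const int CY[8] = {0, 0, 1, 1, 0, 0, 1, 1};
const int CZ[8] = {0, 0, 0, 0, 1, 1, 1, 1};
// 6-tetrahedra decomposition around the 0-6 diagonal; face diagonals are
// consistent between neighbouring cubes.
const int TETS[6][4] = {{0, 5, 1, 6}, {0, 1, 2, 6}, {0, 2, 3, 6},
                        {0, 3, 7, 6}, {0, 7, 4, 6}, {0, 4, 5, 6}};

struct VKey {
  std::uint64_t a, b;
  bool operator==(const VKey& o) const { return a == o.a && b == o.b; }
};
struct VKeyHash {
  size_t operator()(const VKey& k) const {
    return std::hash<std::uint64_t>()(k.a * 1000003ULL ^ k.b);
  }
};

}  // namespace

// Iso-surface of a scalar field sampled at voxel centres, marching
// tetrahedra, vertices in physical mm (centre convention (i+0.5)*h).
// Triangles oriented with outward normal pointing toward decreasing field
// (object = field > level).
// [[Rcpp::export]]
Rcpp::List cpp_march_tets(Rcpp::NumericVector field, Rcpp::IntegerVector dims,
                          Rcpp::NumericVector spacing, double level) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double* F = REAL(field);
  const double hx = spacing[0], hy = spacing[1], hz = spacing[2];

  std::vector<double> VX, VY, VZ;
  std::vector<int> TA, TB, TC;
  std::unordered_map<VKey, int, VKeyHash> edge_vertex;

  auto corner_pos = [&](R_xlen_t cid, double p[3]) {
    int k = (int)(cid / ((R_xlen_t)nx * ny));
    int rem = (int)(cid - (R_xlen_t)k * nx * ny);
    p[0] = ((rem % nx) + 0.5) * hx;
    p[1] = ((rem / nx) + 0.5) * hy;
    p[2] = (k + 0.5) * hz;
  };
  auto edge_point = [&](R_xlen_t c0, R_xlen_t c1) -> int {
    VKey key{(std::uint64_t)std::min(c0, c1), (std::uint64_t)std::max(c0, c1)};
    auto it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double f0 = F[c0], f1 = F[c1];
    double t = (level - f0) / (f1 - f0);
    t = std::min(1.0, std::max(0.0, t));
    double p0[3], p1[3];
    corner_pos(c0, p0);
    corner_pos(c1, p1);
    VX.push_back(p0[0] + t * (p1[0] - p0[0]));
    VY.push_back(p0[1] + t * (p1[1] - p0[1]));
    VZ.push_back(p0[2] + t * (p1[2] - p0[2]));
    int id = (int)VX.size() - 1;
    edge_vertex.emplace(key, id);
    return id;
  };
  auto add_tri = [&](int a, int b, int c, const double g[3]) {
    // orient so normal . g < 0 (outward = decreasing field)
    double ux = VX[b] - VX[a], uy = VY[b] - VY[a], uz = VZ[b] - VZ[a];
    double vx = VX[c] - VX[a], vy = VY[c] - VY[a], vz = VZ[c] - VZ[a];
    double nxn = uy * vz - uz * vy, nyn = uz * vx - ux * vz, nzn = ux * vy - uy * vx;
    if (nxn * g[0] + nyn * g[1] + nzn * g[2] > 0) std::swap(b, c);
    TA.push_back(a); TB.push_back(b); TC.push_back(c);
  };

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        R_xlen_t cid[8];
        double fv[8];
        bool any_hi = false, any_lo = false;
        for (int c = 0; c < 8; ++c) {
          cid[c] = vox_idx(i + CX[c], j + CY[c], k + CZ[c], nx, ny);
          fv[c] = F[cid[c]];
          (fv[c] > level ? any_hi : any_lo) = true;
        }
        if (!any_hi || !any_lo) continue;
        for (int t = 0; t < 6; ++t) {
          const int* tv = TETS[t];
          int above[4], nab = 0;
          for (int c = 0; c < 4; ++c)
            if (fv[tv[c]] > level) above[nab++] = c;
          if (nab == 0 || nab == 4) continue;
          // linear-field gradient inside the tet (physical units)
          double P[4][3], f4[4];
          for (int c = 0; c < 4; ++c) {
            P[c][0] = (i + CX[tv[c]]) * hx;  // relative positions suffice
            P[c][1] = (j + CY[tv[c]]) * hy;
            P[c][2] = (k + CZ[tv[c]]) * hz;
            f4[c] = fv[tv[c]];
          }
          double M[3][3], rhs[3];
          for (int r = 0; r < 3; ++r) {
            for (int cc = 0; cc < 3; ++cc) M[r][cc] = P[r + 1][cc] - P[0][cc];
            rhs[r] = f4[r + 1] - f4[0];
          }
          double det =
              M[0][0] * (M[1][1] * M[2][2] - M[1][2] * M[2][1]) -
              M[0][1] * (M[1][0] * M[2][2] - M[1][2] * M[2][0]) +
              M[0][2] * (M[1][0] * M[2][1] - M[1][1] * M[2][0]);
          double g[3] = {0, 0, 0};
          if (std::fabs(det) > 1e-20) {
            double inv[3][3];
            inv[0][0] = (M[1][1] * M[2][2] - M[1][2] * M[2][1]) / det;
            inv[1][0] = -(M[1][0] * M[2][2] - M[1][2] * M[2][0]) / det;
            inv[2][0] = (M[1][0] * M[2][1] - M[1][1] * M[2][0]) / det;
            inv[0][1] = -(M[0][1] * M[2][2] - M[0][2] * M[2][1]) / det;
            inv[1][1] = (M[0][0] * M[2][2] - M[0][2] * M[2][0]) / det;
            inv[2][1] = -(M[0][0] * M[2][1] - M[0][1] * M[2][0]) / det;
            inv[0][2] = (M[0][1] * M[1][2] - M[0][2] * M[1][1]) / det;
            inv[1][2] = -(M[0][0] * M[1][2] - M[0][2] * M[1][0]) / det;
            inv[2][2] = (M[0][0] * M[1][1] - M[0][1] * M[1][0]) / det;
            for (int r = 0; r < 3; ++r)
              g[r] = inv[r][0] * rhs[0] + inv[r][1] * rhs[1] + inv[r][2] * rhs[2];
          }
          if (nab == 1 || nab == 3) {
            int lone = -1;
            if (nab == 1) lone = above[0];
            else {
              bool isab[4] = {false, false, false, false};
              for (int c = 0; c < nab; ++c) isab[above[c]] = true;
              for (int c = 0; c < 4; ++c) if (!isab[c]) lone = c;
            }
            int o[3], no = 0;
            for (int c = 0; c < 4; ++c) if (c != lone) o[no++] = c;
            int va = edge_point(cid[tv[lone]], cid[tv[o[0]]]);
            int vb = edge_point(cid[tv[lone]], cid[tv[o[1]]]);
            int vc = edge_point(cid[tv[lone]], cid[tv[o[2]]]);
            add_tri(va, vb, vc, g);
          } else {  // 2-2
            int a = above[0], b = above[1];
            int o[2], no = 0;
            for (int c = 0; c < 4; ++c) if (c != a && c != b) o[no++] = c;
            int vac = edge_point(cid[tv[a]], cid[tv[o[0]]]);
            int vad = edge_point(cid[tv[a]], cid[tv[o[1]]]);
            int vbc = edge_point(cid[tv[b]], cid[tv[o[0]]]);
            int vbd = edge_point(cid[tv[b]], cid[tv[o[1]]]);
            add_tri(vac, vad, vbd, g);
            add_tri(vac, vbd, vbc, g);
          }
        }
      }

  int nv = (int)VX.size(), nf = (int)TA.size();
  Rcpp::NumericMatrix V(nv, 3);
  for (int v = 0; v < nv; ++v) { V(v, 0) = VX[v]; V(v, 1) = VY[v]; V(v, 2) = VZ[v]; }
  Rcpp::IntegerMatrix Tm(nf, 3);
  for (int f = 0; f < nf; ++f) {
    Tm(f, 0) = TA[f] + 1; Tm(f, 1) = TB[f] + 1; Tm(f, 2) = TC[f] + 1;
  }
  return Rcpp::List::create(Rcpp::Named("vertices") = V,
                            Rcpp::Named("triangles") = Tm);
}

// Discrete mean curvature: cotangent Laplace-Beltrami with Meyer mixed
// Voronoi areas. H = |K|/2 signed by the angle-weighted vertex normal
// (positive on convex-outward surface patches, e.g. a sphere).
// [[Rcpp::export]]
Rcpp::List cpp_mesh_curvature(Rcpp::NumericMatrix V, Rcpp::IntegerMatrix Tr) {
  const int nv = V.nrow(), nf = Tr.nrow();
  std::vector<double> Kx(nv, 0), Ky(nv, 0), Kz(nv, 0), A(nv, 0);
  std::vector<double> NX(nv, 0), NY(nv, 0), NZ(nv, 0);
  int degenerate = 0;

  auto getp = [&](int v, double p[3]) {
    p[0] = V(v, 0); p[1] = V(v, 1); p[2] = V(v, 2);
  };
  for (int f = 0; f < nf; ++f) {
    int vi[3] = {Tr(f, 0) - 1, Tr(f, 1) - 1, Tr(f, 2) - 1};
    double p[3][3];
    for (int c = 0; c < 3; ++c) getp(vi[c], p[c]);
    // face normal / area
    double u[3] = {p[1][0] - p[0][0], p[1][1] - p[0][1], p[1][2] - p[0][2]};
    double w[3] = {p[2][0] - p[0][0], p[2][1] - p[0][1], p[2][2] - p[0][2]};
    double fn[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                    u[0] * w[1] - u[1] * w[0]};
    double a2 = std::sqrt(fn[0] * fn[0] + fn[1] * fn[1] + fn[2] * fn[2]);
    double area = 0.5 * a2;
    if (area < 1e-14) { ++degenerate; continue; }
    double cot[3], l2[3];
    bool obtuse[3];
    double cosang[3];
    for (int c = 0; c < 3; ++c) {
      int a = vi[c], b = vi[(c + 1) % 3], cc = vi[(c + 2) % 3];
      double e1[3], e2[3];
      for (int d = 0; d < 3; ++d) {
        e1[d] = V(b, d) - V(a, d);
        e2[d] = V(cc, d) - V(a, d);
      }
      double dp = e1[0] * e2[0] + e1[1] * e2[1] + e1[2] * e2[2];
      double cr[3] = {e1[1] * e2[2] - e1[2] * e2[1],
                      e1[2] * e2[0] - e1[0] * e2[2],
                      e1[0] * e2[1] - e1[1] * e2[0]};
      double crn = std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
      cot[c] = crn > 1e-14 ? dp / crn : 0.0;  // cot of angle at vertex c
      cosang[c] = dp;
      obtuse[c] = dp < 0;
      // squared length of edge opposite vertex c (edge b-cc)
      double eo[3];
      for (int d = 0; d < 3; ++d) eo[d] = V(cc, d) - V(b, d);
      l2[c] = eo[0] * eo[0] + eo[1] * eo[1] + eo[2] * eo[2];
    }
    bool any_obtuse = obtuse[0] || obtuse[1] || obtuse[2];
    for (int c = 0; c < 3; ++c) {
      int a = vi[c];
      double va;
      if (!any_obtuse) {
        // Voronoi: 1/8 (|e_ab|^2 cot(angle at cc) + |e_acc|^2 cot(angle at b))
        int b = (c + 1) % 3, cc = (c + 2) % 3;
        double eab = l2[cc];  // edge a-b is opposite vertex cc
        double eac = l2[b];
        va = (eab * cot[cc] + eac * cot[b]) / 8.0;
      } else {
        va = obtuse[c] ? area / 2.0 : area / 4.0;
      }
      A[a] += va;
      NX[a] += fn[0] * (area / a2 * 2.0);  // area-weighted unit normal
      NY[a] += fn[1] * (area / a2 * 2.0);
      NZ[a] += fn[2] * (area / a2 * 2.0);
    }
    // cotangent contributions to K
    for (int c = 0; c < 3; ++c) {
      int opp = vi[c];
      int a = vi[(c + 1) % 3], b = vi[(c + 2) % 3];
      // edge (a, b), angle at opp
      double wgt = cot[c];
      for (int d = 0; d < 3; ++d) {
        double diff = V(a, d) - V(b, d);
        if (d == 0) { Kx[a] += wgt * diff; Kx[b] -= wgt * diff; }
        else if (d == 1) { Ky[a] += wgt * diff; Ky[b] -= wgt * diff; }
        else { Kz[a] += wgt * diff; Kz[b] -= wgt * diff; }
      }
    }
  }
  Rcpp::NumericVector H(nv), Amix(nv);
  for (int v = 0; v < nv; ++v) {
    double a = A[v];
    Amix[v] = a;
    if (a < 1e-14) { H[v] = NA_REAL; continue; }
    double kx = Kx[v] / (2.0 * a), ky = Ky[v] / (2.0 * a), kz = Kz[v] / (2.0 * a);
    double mag = 0.5 * std::sqrt(kx * kx + ky * ky + kz * kz);
    double sgn = kx * NX[v] + ky * NY[v] + kz * NZ[v];
    H[v] = sgn >= 0 ? mag : -mag;
  }
  return Rcpp::List::create(Rcpp::Named("H") = H,
                            Rcpp::Named("area") = Amix,
                            Rcpp::Named("degenerate") = degenerate);
}

// Uniform Laplacian smoothing with fixed step; caller checks volume drift.
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_mesh_smooth(Rcpp::NumericMatrix V,
                                    Rcpp::IntegerMatrix Tr, int iters,
                                    double lambda) {
  const int nv = V.nrow(), nf = Tr.nrow();
  std::vector<std::vector<int>> nb(nv);
  for (int f = 0; f < nf; ++f) {
    int a = Tr(f, 0) - 1, b = Tr(f, 1) - 1, c = Tr(f, 2) - 1;
    nb[a].push_back(b); nb[a].push_back(c);
    nb[b].push_back(a); nb[b].push_back(c);
    nb[c].push_back(a); nb[c].push_back(b);
  }
  Rcpp::NumericMatrix out(Rcpp::clone(V));
  Rcpp::NumericMatrix tmp(nv, 3);
  for (int it = 0; it < iters; ++it) {
    for (int v = 0; v < nv; ++v) {
      if (nb[v].empty()) {
        for (int d = 0; d < 3; ++d) tmp(v, d) = out(v, d);
        continue;
      }
      double m[3] = {0, 0, 0};
      for (int u : nb[v])
        for (int d = 0; d < 3; ++d) m[d] += out(u, d);
      for (int d = 0; d < 3; ++d) {
        m[d] /= nb[v].size();
        tmp(v, d) = out(v, d) + lambda * (m[d] - out(v, d));
      }
    }
    std::copy(tmp.begin(), tmp.end(), out.begin());
  }
  return out;
}

// Iterated neighbour averaging of a per-vertex scalar (e.g. mean curvature
// before forming curvature energy integrals); NA values are rebuilt from
// their neighbours.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_smooth_vertex_field(Rcpp::IntegerMatrix Tr, int nv,
                                            Rcpp::NumericVector values,
                                            int iters) {
  const int nf = Tr.nrow();
  std::vector<std::vector<int>> nb(nv);
  for (int f = 0; f < nf; ++f) {
    int a = Tr(f, 0) - 1, b = Tr(f, 1) - 1, c = Tr(f, 2) - 1;
    nb[a].push_back(b); nb[a].push_back(c);
    nb[b].push_back(a); nb[b].push_back(c);
    nb[c].push_back(a); nb[c].push_back(b);
  }
  std::vector<double> cur(values.begin(), values.end()), nxt(nv);
  for (int it = 0; it < iters; ++it) {
    for (int v = 0; v < nv; ++v) {
      double s = 0; int cnt = 0;
      for (int u : nb[v]) {
        if (!ISNAN(cur[u])) { s += cur[u]; ++cnt; }
      }
      nxt[v] = cnt > 0 ? s / cnt : cur[v];
    }
    std::swap(cur, nxt);
  }
  return Rcpp::NumericVector(cur.begin(), cur.end());
}

// Total area, signed enclosed volume (divergence theorem) and boundary-edge
// count (0 for a closed surface).
// [[Rcpp::export]]
Rcpp::List cpp_mesh_measures(Rcpp::NumericMatrix V, Rcpp::IntegerMatrix Tr) {
  const int nf = Tr.nrow();
  double area = 0, vol = 0;
  std::unordered_map<std::uint64_t, int> ecount;
  ecount.reserve(nf * 2);
  for (int f = 0; f < nf; ++f) {
    int a = Tr(f, 0) - 1, b = Tr(f, 1) - 1, c = Tr(f, 2) - 1;
    double p0[3] = {V(a, 0), V(a, 1), V(a, 2)};
    double p1[3] = {V(b, 0), V(b, 1), V(b, 2)};
    double p2[3] = {V(c, 0), V(c, 1), V(c, 2)};
    double u[3] = {p1[0] - p0[0], p1[1] - p0[1], p1[2] - p0[2]};
    double w[3] = {p2[0] - p0[0], p2[1] - p0[1], p2[2] - p0[2]};
    double cr[3] = {u[1] * w[2] - u[2] * w[1], u[2] * w[0] - u[0] * w[2],
                    u[0] * w[1] - u[1] * w[0]};
    area += 0.5 * std::sqrt(cr[0] * cr[0] + cr[1] * cr[1] + cr[2] * cr[2]);
    vol += (p0[0] * (p1[1] * p2[2] - p1[2] * p2[1]) -
            p0[1] * (p1[0] * p2[2] - p1[2] * p2[0]) +
            p0[2] * (p1[0] * p2[1] - p1[1] * p2[0])) / 6.0;
    int vv[3] = {a, b, c};
    for (int s = 0; s < 3; ++s) {
      int x = vv[s], y = vv[(s + 1) % 3];
      std::uint64_t key = ((std::uint64_t)std::min(x, y) << 32) |
                          (std::uint64_t)std::max(x, y);
      ecount[key]++;
    }
  }
  int boundary = 0, nonmanifold = 0;
  for (auto& kv : ecount) {
    if (kv.second == 1) ++boundary;
    else if (kv.second > 2) ++nonmanifold;
  }
  return Rcpp::List::create(Rcpp::Named("area") = area,
                            Rcpp::Named("volume") = vol,
                            Rcpp::Named("boundary_edges") = boundary,
                            Rcpp::Named("nonmanifold_edges") = nonmanifold,
                            Rcpp::Named("edges") = (int)ecount.size());
}
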