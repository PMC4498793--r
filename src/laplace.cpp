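#include "morph.h"
using namespace Rcpp;

// Discrete Laplace equation on the CoGM domain, physical coordinates,
// anisotropic 7-point stencil. Dirichlet data live on the tissue *faces*:
// links to an inner (UWM) or outer (CSF/BG) neighbour use half spacing, so
// psi = 0 / 1 is imposed at the boundary face, not at the neighbour centre.
// Red-black SOR. Labels: 0 BG, 1 UWM, 2 CoGM, 3 CSF (4 OTHER treated as BG).
// [[Rcpp::export]]
Rcpp::List cpp_solve_laplace(Rcpp::IntegerVector labels,
                             Rcpp::IntegerVector dims,
                             Rcpp::NumericVector spacing, double tol,
                             int max_iter, double omega) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const double w_in[3] = {1.0 / (spacing[0] * spacing[0]),
                          1.0 / (spacing[1] * spacing[1]),
                          1.0 / (spacing[2] * spacing[2])};

  std::vector<R_xlen_t> dom;   // CoGM voxel linear indices
  dom.reserve(1 << 20);
  Rcpp::IntegerVector tags(n, -1);  // -1 non-CoGM, 0 interior, 1 inner, 2 outer, 3 both
  Rcpp::NumericVector psi(n);
  psi.attr("dim") = dims;
  tags.attr("dim") = dims;

  for (R_xlen_t t = 0; t < n; ++t)
    psi[t] = (labels[t] == 2) ? 0.5 : (labels[t] == 1 ? 0.0 : 1.0);

  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};

  long n_inner_faces = 0, n_outer_faces = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = vox_idx(i, j, k, nx, ny);
        if (labels[t] != 2) continue;
        dom.push_back(t);
        bool inner = false, outer = false;
        for (int d = 0; d < 6; ++d) {
          int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            continue;  // grid truncation: zero-flux, not a tissue boundary
          int lb = labels[vox_idx(ii, jj, kk, nx, ny)];
          if (lb == 1) { inner = true; ++n_inner_faces; }
          else if (lb != 2) { outer = true; ++n_outer_faces; }
        }
        tags[t] = inner && outer ? 3 : (inner ? 1 : (outer ? 2 : 0));
      }
  if (dom.empty()) Rcpp::stop("no CoGM voxels in label map");
  if (n_inner_faces == 0 || n_outer_faces == 0)
    Rcpp::stop("CoGM has no %s boundary; cannot pose the Laplace problem",
               n_inner_faces == 0 ? "inner (UWM)" : "outer (CSF/background)");

  // precompute per-domain-voxel ijk parity for red-black ordering
  std::vector<unsigned char> parity(dom.size());
  for (size_t s = 0; s < dom.size(); ++s) {
    R_xlen_t t = dom[s];
    int k = (int)(t / ((R_xlen_t)nx * ny));
    int rem = (int)(t - (R_xlen_t)k * nx * ny);
    parity[s] = (unsigned char)(((rem % nx) + (rem / nx) + k) & 1);
  }

  double maxres = R_PosInf;
  int it = 0;
  const R_xlen_t stride[6] = {-1, 1, -(R_xlen_t)nx, (R_xlen_t)nx,
                              -(R_xlen_t)nx * ny, (R_xlen_t)nx * ny};
  auto sweep = [&](int col, bool record) {
    double mr = 0.0;
    for (size_t s = 0; s < dom.size(); ++s) {
      if (parity[s] != col) continue;
      R_xlen_t t = dom[s];
      int k = (int)(t / ((R_xlen_t)nx * ny));
      int rem = (int)(t - (R_xlen_t)k * nx * ny);
      int i = rem % nx, j = rem / nx;
      double num = 0.0, den = 0.0;
      for (int d = 0; d < 6; ++d) {
        int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
        if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
          continue;  // zero-flux at grid truncation
        int ax = NB_AXIS[d];
        R_xlen_t tt = t + stride[d];
        int lb = labels[tt];
        // boundary faces sit half a voxel away: flux (psi_b - psi)/(h/2)
        // through area 1/h gives a 2/h^2 link weight
        double val = (lb == 2) ? psi[tt] : (lb == 1 ? 0.0 : 1.0);
        double w = (lb == 2) ? w_in[ax] : 2.0 * w_in[ax];
        num += w * val;
        den += w;
      }
      if (den <= 0) continue;
      double upd = num / den;
      double r = upd - psi[t];
      if (record) mr = std::max(mr, std::fabs(r));
      psi[t] += omega * r;
    }
    return mr;
  };

  while (it < max_iter) {
    bool record = (it % 10 == 9);
    double r0 = sweep(0, record);
    double r1 = sweep(1, record);
    ++it;
    if (record) {
      maxres = std::max(r0, r1);
      if (maxres < tol) break;
    }
  }
  // clamp tiny overshoot from over-relaxation
  for (R_xlen_t s = 0; s < (R_xlen_t)dom.size(); ++s) {
    R_xlen_t t = dom[s];
    if (psi[t] < 0) psi[t] = 0;
    if (psi[t] > 1) psi[t] = 1;
  }
  return Rcpp::List::create(Rcpp::Named("psi") = psi,
                            Rcpp::Named("tags") = tags,
                            Rcpp::Named("iterations") = it,
                            Rcpp::Named("residual") = maxres,
                            Rcpp::Named("converged") = maxres < tol);
}

namespace {

struct Interp {
  const double* psi;
  int nx, ny, nz;
  const double* h;
  // trilinear value and gradient (physical units) at point p (mm, corner origin)
  bool eval(const double p[3], double& val, double g[3]) const {
    double u[3];
    int base[3];
    const int nn[3] = {nx, ny, nz};
    for (int d = 0; d < 3; ++d) {
      double s = p[d] / h[d] - 0.5;
      int b = (int)std::floor(s);
      if (b < 0) { b = 0; s = 0; }
      if (b > nn[d] - 2) { b = nn[d] - 2; s = (double)(nn[d] - 1); }
      base[d] = b;
      u[d] = s - b;
      if (u[d] < 0) u[d] = 0;
      if (u[d] > 1) u[d] = 1;
    }
    double c[2][2][2];
    for (int a = 0; a < 2; ++a)
      for (int b2 = 0; b2 < 2; ++b2)
        for (int c2 = 0; c2 < 2; ++c2)
          c[a][b2][c2] = psi[vox_idx(base[0] + a, base[1] + b2, base[2] + c2, nx, ny)];
    double ux = u[0], uy = u[1], uz = u[2];
    auto lerp = [](double a, double b, double t) { return a + (b - a) * t; };
    // value
    double c00 = lerp(c[0][0][0], c[1][0][0], ux);
    double c10 = lerp(c[0][1][0], c[1][1][0], ux);
    double c01 = lerp(c[0][0][1], c[1][0][1], ux);
    double c11 = lerp(c[0][1][1], c[1][1][1], ux);
    double c0 = lerp(c00, c10, uy), c1 = lerp(c01, c11, uy);
    val = lerp(c0, c1, uz);
    // gradient
    double gx0 = lerp(c[1][0][0] - c[0][0][0], c[1][1][0] - c[0][1][0], uy);
    double gx1 = lerp(c[1][0][1] - c[0][0][1], c[1][1][1] - c[0][1][1], uy);
    g[0] = lerp(gx0, gx1, uz) / h[0];
    double gy0 = lerp(c[0][1][0] - c[0][0][0], c[1][1][0] - c[1][0][0], ux);
    double gy1 = lerp(c[0][1][1] - c[0][0][1], c[1][1][1] - c[1][0][1], ux);
    g[1] = lerp(gy0, gy1, uz) / h[1];
    double gz00 = c[0][0][1] - c[0][0][0], gz10 = c[1][0][1] - c[1][0][0];
    double gz01 = c[0][1][1] - c[0][1][0], gz11 = c[1][1][1] - c[1][1][0];
    g[2] = lerp(lerp(gz00, gz10, ux), lerp(gz01, gz11, ux), uy) / h[2];
    return true;
  }
};

}  // namespace

// Streamline thickness per CoGM voxel: integrate the normalized gradient of
// psi forward (to the outer boundary) and backward (to the inner boundary),
// midpoint rule, clipping the final segment at the tissue face. Reason codes:
// 0 valid, 1 stationary (|grad| ~ 0), 2 runaway (length cap), 3 wrong-side
// exit, 4 one-voxel cortex pinned between both boundaries (face-to-face
// distance used instead of a streamline).
// [[Rcpp::export]]
Rcpp::List cpp_streamline_thickness(Rcpp::NumericVector psi,
                                    Rcpp::IntegerVector labels,
                                    Rcpp::IntegerVector tags,
                                    Rcpp::IntegerVector dims,
                                    Rcpp::NumericVector spacing, double step,
                                    double cap) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector thick(n, NA_REAL);
  Rcpp::IntegerVector reason(n, NA_INTEGER);
  thick.attr("dim") = dims;
  reason.attr("dim") = dims;
  Interp ip{REAL(psi), nx, ny, nz, REAL(spacing)};
  const double* h = REAL(spacing);
  const double gmin = 1e-8;

  auto label_at = [&](const double p[3], int idx[3]) -> int {
    for (int d = 0; d < 3; ++d) {
      int nn = d == 0 ? nx : (d == 1 ? ny : nz);
      idx[d] = (int)std::floor(p[d] / h[d]);
      if (idx[d] < 0 || idx[d] >= nn) return 0;  // outside grid: background
    }
    return labels[vox_idx(idx[0], idx[1], idx[2], nx, ny)];
  };

  // trace from the centre of voxel (i,j,k) along sgn * normalized grad(psi)
  auto trace = [&](int i, int j, int k, int sgn, double& len) -> int {
    double p[3] = {(i + 0.5) * h[0], (j + 0.5) * h[1], (k + 0.5) * h[2]};
    len = 0.0;
    int idx0[3] = {i, j, k};
    while (len < cap) {
      double val, g[3];
      ip.eval(p, val, g);
      double gn = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
      if (gn < gmin) return 1;
      double dir[3] = {sgn * g[0] / gn, sgn * g[1] / gn, sgn * g[2] / gn};
      // midpoint evaluation
      double pm[3] = {p[0] + 0.5 * step * dir[0], p[1] + 0.5 * step * dir[1],
                      p[2] + 0.5 * step * dir[2]};
      double valm, gm[3];
      ip.eval(pm, valm, gm);
      double gmn = std::sqrt(gm[0] * gm[0] + gm[1] * gm[1] + gm[2] * gm[2]);
      if (gmn > gmin) {
        dir[0] = sgn * gm[0] / gmn; dir[1] = sgn * gm[1] / gmn;
        dir[2] = sgn * gm[2] / gmn;
      }
      double pn[3] = {p[0] + step * dir[0], p[1] + step * dir[1],
                      p[2] + step * dir[2]};
      int idx1[3];
      int lb = label_at(pn, idx1);
      if (lb != 2) {
        // clip at the face of the voxel we left
        double tmin = 1.0;
        for (int d = 0; d < 3; ++d) {
          if (idx1[d] == idx0[d]) continue;
          double face = (idx1[d] > idx0[d] ? idx0[d] + 1.0 : (double)idx0[d]) * h[d];
          double dp = pn[d] - p[d];
          if (std::fabs(dp) > 1e-12) {
            double tt = (face - p[d]) / dp;
            if (tt > 0 && tt < tmin) tmin = tt;
          }
        }
        len += tmin * step;
        bool want_inner = (sgn < 0);
        bool ok = want_inner ? (lb == 1) : (lb == 0 || lb == 3 || lb == 4);
        return ok ? 0 : 3;
      }
      len += step;
      p[0] = pn[0]; p[1] = pn[1]; p[2] = pn[2];
      idx0[0] = idx1[0]; idx0[1] = idx1[1]; idx0[2] = idx1[2];
    }
    return 2;
  };

  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = vox_idx(i, j, k, nx, ny);
        if (labels[t] != 2) continue;
        if (tags[t] == 3) {
          // pinned: half-link to each boundary face along the thinnest axis
          double best = R_PosInf;
          const int di[6] = {-1, 1, 0, 0, 0, 0};
          const int dj[6] = {0, 0, -1, 1, 0, 0};
          const int dk[6] = {0, 0, 0, 0, -1, 1};
          double din = R_PosInf, dout = R_PosInf;
          for (int d = 0; d < 6; ++d) {
            int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            int lb = labels[vox_idx(ii, jj, kk, nx, ny)];
            double hd = 0.5 * h[NB_AXIS[d]];
            if (lb == 1) din = std::min(din, hd);
            else if (lb != 2) dout = std::min(dout, hd);
          }
          best = din + dout;
          thick[t] = best;
          reason[t] = 4;
          continue;
        }
        double lf = 0, lb2 = 0;
        int rf = trace(i, j, k, +1, lf);
        int rb = rf == 0 ? trace(i, j, k, -1, lb2) : rf;
        if (rf == 0 && rb == 0) {
          thick[t] = lf + lb2;
          reason[t] = 0;
        } else {
          reason[t] = rf != 0 ? rf : rb;
        }
      }
  return Rcpp::List::create(Rcpp::Named("thickness") = thick,
                            Rcpp::Named("reason") = reason);
}
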