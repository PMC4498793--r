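#include "morph.h"
using namespace Rcpp;

// Fold shaping: monotone map of u = sin(l*theta)*sin(m*phi) in [-1,1] onto
// [-1,1]. w is the wall sharpness (w -> Inf reduces to the identity, i.e. the
// pure sinusoid); b shifts the zero crossing so gyral plateaus and sulcal
// slots can have unequal widths.
static inline double fold_shape(double u, double w, double b) {
  if (!std::isfinite(w) || w <= 0.0 || w > 50.0) return u;
  double np = std::tanh((1.0 - b) / w);
  double nm = std::tanh((1.0 + b) / w);
  return 2.0 * (std::tanh((u - b) / w) + nm) / (np + nm) - 1.0;
}

// [[Rcpp::export]]
double cpp_fold_shape(double u, double w, double b) { return fold_shape(u, w, b); }

// Radius of the inner (UWM) surface in direction (theta, phi).
static inline double fold_radius(double theta, double phi, double R0, double a,
                                 double l, double m, double w, double b) {
  double u = std::sin(l * theta) * std::sin(m * phi);
  return R0 * (1.0 + a * fold_shape(u, w, b));
}

// [[Rcpp::export]]
Rcpp::NumericVector cpp_fold_radius(Rcpp::NumericVector theta,
                                    Rcpp::NumericVector phi, double R0,
                                    double a, double l, double m, double w,
                                    double b) {
  R_xlen_t n = theta.size();
  Rcpp::NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = fold_radius(theta[i], phi[i], R0, a, l, m, w, b);
  return out;
}

// Voxelize the two-shell phantom. Voxel centre of index (i,j,k) (0-based)
// sits at (i+0.5)*spacing - centre, physical mm. Labels: 0 BG, 1 UWM,
// 2 CoGM (0 < dist(UWM) <= t_cx), 3 CSF (t_cx < dist <= t_cx + t_csf).
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_phantom_labels(Rcpp::IntegerVector dims,
                                       Rcpp::NumericVector spacing,
                                       Rcpp::NumericVector centre, double R0,
                                       double a, double l, double m, double w,
                                       double b, double t_cx, double t_csf,
                                       double edge_corr_vox) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::IntegerVector labels(n);
  std::vector<int> uwm(n, 0);
  for (int k = 0; k < nz; ++k) {
    double z = (k + 0.5) * spacing[2] - centre[2];
    for (int j = 0; j < ny; ++j) {
      double y = (j + 0.5) * spacing[1] - centre[1];
      for (int i = 0; i < nx; ++i) {
        double x = (i + 0.5) * spacing[0] - centre[0];
        double r = std::sqrt(x * x + y * y + z * z);
        double rho;
        if (r < 1e-9) {
          rho = R0 * (1.0 - std::fabs(a));  // safely inside
          uwm[vox_idx(i, j, k, nx, ny)] = 1;
          continue;
        }
        double theta = std::acos(std::min(1.0, std::max(-1.0, z / r)));
        double phi = std::atan2(y, x);
        rho = fold_radius(theta, phi, R0, a, l, m, w, b);
        if (r <= rho) uwm[vox_idx(i, j, k, nx, ny)] = 1;
      }
    }
  }
  std::vector<double> d2(n);
  edt_squared(uwm.data(), INTEGER(dims), REAL(spacing), d2.data(), nullptr);
  // the EDT measures to voxel centres, which sit below the analytic surface
  // by ~a quarter voxel on average; widen the band accordingly so the outer
  // offset surfaces sit at their geometric distances
  const double corr =
      edge_corr_vox * (spacing[0] + spacing[1] + spacing[2]) / 3.0;
  const double t1 = (t_cx + corr) * (t_cx + corr);
  const double t2 = (t_cx + t_csf + corr) * (t_cx + t_csf + corr);
  for (R_xlen_t t = 0; t < n; ++t) {
    if (uwm[t]) labels[t] = 1;
    else if (d2[t] <= t1) labels[t] = 2;
    else if (d2[t] <= t2) labels[t] = 3;
    else labels[t] = 0;
  }
  labels.attr("dim") = dims;
  return labels;
}

// Nearest-neighbour label resampling in physical space. Both grids use the
// voxel-centre convention centre = origin + (idx + 0.5) * spacing.
// [[Rcpp::export]]
Rcpp::IntegerVector cpp_resample_nn(Rcpp::IntegerVector values,
                                    Rcpp::IntegerVector dims,
                                    Rcpp::NumericVector spacing,
                                    Rcpp::IntegerVector new_dims,
                                    Rcpp::NumericVector new_spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int mx = new_dims[0], my = new_dims[1], mz = new_dims[2];
  Rcpp::IntegerVector out((R_xlen_t)mx * my * mz);
  for (int k = 0; k < mz; ++k) {
    int sk = (int)std::floor((k + 0.5) * new_spacing[2] / spacing[2]);
    sk = std::min(nz - 1, std::max(0, sk));
    for (int j = 0; j < my; ++j) {
      int sj = (int)std::floor((j + 0.5) * new_spacing[1] / spacing[1]);
      sj = std::min(ny - 1, std::max(0, sj));
      for (int i = 0; i < mx; ++i) {
        int si = (int)std::floor((i + 0.5) * new_spacing[0] / spacing[0]);
        si = std::min(nx - 1, std::max(0, si));
        out[vox_idx(i, j, k, mx, my)] = values[vox_idx(si, sj, sk, nx, ny)];
      }
    }
  }
  out.attr("dim") = new_dims;
  return out;
}
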