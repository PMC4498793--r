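#include "morph.h"
using namespace Rcpp;

// Felzenszwalb & Huttenlocher lower-envelope distance transform along one
// axis. Sample positions are q*h; g holds incoming squared distances and is
// overwritten. site carries the nearest-voxel linear index through the pass.
static void dt1d(std::vector<double>& g, std::vector<R_xlen_t>& site,
                 int n, double h) {
  const double INF = std::numeric_limits<double>::infinity();
  static thread_local std::vector<int> v;
  static thread_local std::vector<double> z, f;
  static thread_local std::vector<R_xlen_t> s0;
  v.assign(n, 0); z.assign(n + 1, 0.0);
  f.assign(g.begin(), g.begin() + n);
  s0.assign(site.begin(), site.begin() + n);

  const double h2 = h * h;
  int k = 0;
  bool any = false;
  // Work in index units: parabola q has height f[q]/h2. z[0] = -INF keeps the
  // envelope loop from underflowing k.
  auto isect = [&](int q, int p) {
    return ((f[q] / h2 + (double)q * q) - (f[p] / h2 + (double)p * p)) /
           (2.0 * (q - p));
  };
  for (int q = 0; q < n; ++q) {
    if (!std::isfinite(f[q])) continue;
    if (!any) {
      v[0] = q; z[0] = -INF; z[1] = INF; k = 0; any = true;
      continue;
    }
    double s = isect(q, v[k]);
    while (s <= z[k]) { --k; s = isect(q, v[k]); }
    ++k;
    v[k] = q; z[k] = s; z[k + 1] = INF;
  }
  if (!any) { std::fill(g.begin(), g.begin() + n, INF); return; }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < (double)q) ++k;
    int p = v[k];
    double dq = (double)(q - p);
    g[q] = dq * dq * h2 + f[p];
    site[q] = s0[p];
  }
}

void edt_squared(const int* mask, const int* dims, const double* spacing,
                 double* d2, R_xlen_t* feat) {
  const double INF = std::numeric_limits<double>::infinity();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<R_xlen_t> site(n);
  for (R_xlen_t t = 0; t < n; ++t) {
    d2[t] = mask[t] ? 0.0 : INF;
    site[t] = mask[t] ? t : (R_xlen_t)(-1);
  }
  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> line(nmax);
  std::vector<R_xlen_t> lsite(nmax);
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = vox_idx(0, j, k, nx, ny);
      for (int i = 0; i < nx; ++i) { line[i] = d2[base + i]; lsite[i] = site[base + i]; }
      dt1d(line, lsite, nx, spacing[0]);
      for (int i = 0; i < nx; ++i) { d2[base + i] = line[i]; site[base + i] = lsite[i]; }
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) {
        R_xlen_t t = vox_idx(i, j, k, nx, ny);
        line[j] = d2[t]; lsite[j] = site[t];
      }
      dt1d(line, lsite, ny, spacing[1]);
      for (int j = 0; j < ny; ++j) {
        R_xlen_t t = vox_idx(i, j, k, nx, ny);
        d2[t] = line[j]; site[t] = lsite[j];
      }
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) {
        R_xlen_t t = vox_idx(i, j, k, nx, ny);
        line[k] = d2[t]; lsite[k] = site[t];
      }
      dt1d(line, lsite, nz, spacing[2]);
      for (int k = 0; k < nz; ++k) {
        R_xlen_t t = vox_idx(i, j, k, nx, ny);
        d2[t] = line[k]; site[t] = lsite[k];
      }
    }
  if (feat) std::copy(site.begin(), site.end(), feat);
}

// [[Rcpp::export]]
Rcpp::List cpp_edt(Rcpp::IntegerVector mask, Rcpp::IntegerVector dims,
                   Rcpp::NumericVector spacing, bool feature = false) {
  const R_xlen_t n = (R_xlen_t)dims[0] * dims[1] * dims[2];
  Rcpp::NumericVector d2(n);
  std::vector<R_xlen_t> feat;
  if (feature) feat.resize(n);
  edt_squared(INTEGER(mask), INTEGER(dims), REAL(spacing), REAL(d2),
              feature ? feat.data() : nullptr);
  Rcpp::NumericVector d(n);
  for (R_xlen_t t = 0; t < n; ++t) d[t] = std::sqrt(d2[t]);
  if (!feature) return Rcpp::List::create(Rcpp::Named("dist") = d);
  Rcpp::NumericVector fi(n);  // 1-based nearest-voxel index (double: may exceed int)
  for (R_xlen_t t = 0; t < n; ++t) fi[t] = feat[t] >= 0 ? (double)(feat[t] + 1) : NA_REAL;
  return Rcpp::List::create(Rcpp::Named("dist") = d, Rcpp::Named("nearest") = fi);
}
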