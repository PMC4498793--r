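#include "morph.h"
using namespace Rcpp;

// Separable Gaussian smoothing, sigma in voxel units per axis, reflected
// boundaries. Used for surfel-normal estimation and iso-surface extraction.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_gauss_smooth(Rcpp::NumericVector x,
                                     Rcpp::IntegerVector dims,
                                     Rcpp::NumericVector sigma) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  Rcpp::NumericVector out(Rcpp::clone(x));
  out.attr("dim") = dims;
  const int nn[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma[axis];
    if (s <= 0) continue;
    int rad = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * rad + 1);
    double sum = 0;
    for (int t = -rad; t <= rad; ++t) {
      kern[t + rad] = std::exp(-0.5 * t * t / (s * s));
      sum += kern[t + rad];
    }
    for (auto& v : kern) v /= sum;
    const int len = nn[axis];
    std::vector<double> buf(len);
    R_xlen_t stride = axis == 0 ? 1 : (axis == 1 ? nx : (R_xlen_t)nx * ny);
    int n1 = axis == 0 ? ny : nx;
    int n2 = axis == 2 ? ny : nz;
    R_xlen_t s1 = axis == 0 ? nx : 1;
    R_xlen_t s2 = axis == 2 ? nx : (R_xlen_t)nx * ny;
    for (int b = 0; b < n2; ++b)
      for (int a2 = 0; a2 < n1; ++a2) {
        R_xlen_t base = a2 * s1 + b * s2;
        for (int t = 0; t < len; ++t) buf[t] = out[base + t * stride];
        for (int t = 0; t < len; ++t) {
          double acc = 0;
          for (int u = -rad; u <= rad; ++u) {
            int p = t + u;
            if (p < 0) p = -p - 1;          // reflect
            if (p >= len) p = 2 * len - p - 1;
            acc += kern[u + rad] * buf[p];
          }
          out[base + t * stride] = acc;
        }
      }
  }
  return out;
}

// One surfel per 6-adjacent voxel face between label set A and label set B.
// Returns 0-based linear index of the A-side voxel and the face direction
// (0..5 = -x,+x,-y,+y,-z,+z). Faces to outside the grid count as B when
// `outside_b` (background outside the volume).
// [[Rcpp::export]]
Rcpp::IntegerMatrix cpp_boundary_faces(Rcpp::IntegerVector labels,
                                       Rcpp::IntegerVector dims,
                                       Rcpp::IntegerVector set_a,
                                       Rcpp::IntegerVector set_b,
                                       bool outside_b = false) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<bool> in_a(256, false), in_b(256, false);
  for (int v : set_a) if (v >= 0 && v < 256) in_a[v] = true;
  for (int v : set_b) if (v >= 0 && v < 256) in_b[v] = true;
  std::vector<int> fi, fd;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        R_xlen_t t = vox_idx(i, j, k, nx, ny);
        int lv = labels[t];
        if (lv < 0 || lv > 255 || !in_a[lv]) continue;
        const int di[6] = {-1, 1, 0, 0, 0, 0};
        const int dj[6] = {0, 0, -1, 1, 0, 0};
        const int dk[6] = {0, 0, 0, 0, -1, 1};
        for (int d = 0; d < 6; ++d) {
          int ii = i + di[d], jj = j + dj[d], kk = k + dk[d];
          bool is_b;
          if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
            is_b = outside_b;
          else {
            int lb = labels[vox_idx(ii, jj, kk, nx, ny)];
            is_b = lb >= 0 && lb < 256 && in_b[lb];
          }
          if (is_b) { fi.push_back((int)t); fd.push_back(d); }
        }
      }
  Rcpp::IntegerMatrix out(fi.size(), 2);
  for (size_t r = 0; r < fi.size(); ++r) { out(r, 0) = fi[r]; out(r, 1) = fd[r]; }
  return out;
}

// Configuration weight of each surfel: |n-hat . e-hat| where n-hat is the
// object-surface normal estimated from the smoothed occupancy field G at the
// face centre. Exact for axis-aligned and oblique planes; the weight of a
// surfel is a function of its local neighbourhood configuration through G.
// [[Rcpp::export]]
Rcpp::NumericVector cpp_face_weights(Rcpp::NumericVector G,
                                     Rcpp::IntegerVector dims,
                                     Rcpp::IntegerMatrix faces) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nface = faces.nrow();
  Rcpp::NumericVector w(nface);

  auto gval = [&](int i, int j, int k) -> double {
    i = std::min(nx - 1, std::max(0, i));
    j = std::min(ny - 1, std::max(0, j));
    k = std::min(nz - 1, std::max(0, k));
    return G[vox_idx(i, j, k, nx, ny)];
  };
  // central-difference gradient (index units; isotropic spacing assumed by
  // the caller so the common factor cancels in the normalization)
  auto grad_at = [&](int i, int j, int k, double g[3]) {
    g[0] = 0.5 * (gval(i + 1, j, k) - gval(i - 1, j, k));
    g[1] = 0.5 * (gval(i, j + 1, k) - gval(i, j - 1, k));
    g[2] = 0.5 * (gval(i, j, k + 1) - gval(i, j, k - 1));
  };
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t f = 0; f < nface; ++f) {
    R_xlen_t t = faces(f, 0);
    int d = faces(f, 1);
    int k = (int)(t / ((R_xlen_t)nx * ny));
    int rem = (int)(t - (R_xlen_t)k * nx * ny);
    int j = rem / nx, i = rem % nx;
    double ga[3], gb[3];
    grad_at(i, j, k, ga);
    grad_at(i + di[d], j + dj[d], k + dk[d], gb);
    double g[3] = {0.5 * (ga[0] + gb[0]), 0.5 * (ga[1] + gb[1]),
                   0.5 * (ga[2] + gb[2])};
    double norm = std::sqrt(g[0] * g[0] + g[1] * g[1] + g[2] * g[2]);
    int ax = NB_AXIS[d];
    w[f] = norm > 1e-12 ? std::fabs(g[ax]) / norm : 1.0;
  }
  return w;
}
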