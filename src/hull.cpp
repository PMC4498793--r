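#include "morph.h"
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};
static inline Vec3 sub(const Vec3& a, const Vec3& b) {
  return {a.x - b.x, a.y - b.y, a.z - b.z};
}
static inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return {a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x};
}
static inline double dot(const Vec3& a, const Vec3& b) {
  return a.x * b.x + a.y * b.y + a.z * b.z;
}
static inline double norm(const Vec3& a) { return std::sqrt(dot(a, a)); }

struct Face {
  int v[3];
  Vec3 n;       // unit outward normal
  double off;   // plane offset: dot(n, x) = off on the face
  bool alive = true;
  std::vector<int> conflicts;
  int far_p = -1;
  double far_d = 0.0;
};

struct HullBuilder {
  const std::vector<Vec3>& P;
  std::vector<Face> faces;
  Vec3 inner{0, 0, 0};
  double eps;

  explicit HullBuilder(const std::vector<Vec3>& pts, double eps_) : P(pts), eps(eps_) {}

  double dist(const Face& f, int p) const { return dot(f.n, P[p]) - f.off; }

  bool make_face(int a, int b, int c) {
    Face f;
    f.v[0] = a; f.v[1] = b; f.v[2] = c;
    Vec3 nn = cross(sub(P[b], P[a]), sub(P[c], P[a]));
    double ln = norm(nn);
    if (ln < 1e-14) return false;
    f.n = {nn.x / ln, nn.y / ln, nn.z / ln};
    f.off = dot(f.n, P[a]);
    if (dot(f.n, inner) - f.off > 0) {  // flip to point away from interior
      std::swap(f.v[1], f.v[2]);
      f.n = {-f.n.x, -f.n.y, -f.n.z};
      f.off = -f.off;
    }
    faces.push_back(std::move(f));
    return true;
  }

  void assign(const std::vector<int>& pts, std::vector<Face*>& targets) {
    for (int p : pts) {
      for (Face* f : targets) {
        double d = dot(f->n, P[p]) - f->off;
        if (d > eps) {
          f->conflicts.push_back(p);
          if (d > f->far_d) { f->far_d = d; f->far_p = p; }
          break;
        }
      }
    }
  }

  bool build() {
    const int n = (int)P.size();
    if (n < 4) return false;
    // extreme initial simplex
    int i0 = 0, i1 = 0;
    for (int d = 0; d < 3; ++d) {
      int lo = 0, hi = 0;
      for (int p = 1; p < n; ++p) {
        double vlo = d == 0 ? P[lo].x : (d == 1 ? P[lo].y : P[lo].z);
        double vhi = d == 0 ? P[hi].x : (d == 1 ? P[hi].y : P[hi].z);
        double vp = d == 0 ? P[p].x : (d == 1 ? P[p].y : P[p].z);
        if (vp < vlo) lo = p;
        if (vp > vhi) hi = p;
      }
      Vec3 dd = sub(P[hi], P[lo]);
      if (norm(dd) > norm(sub(P[i1], P[i0]))) { i0 = lo; i1 = hi; }
    }
    if (norm(sub(P[i1], P[i0])) < 1e-12) return false;
    Vec3 e = sub(P[i1], P[i0]);
    int i2 = -1; double best = eps;
    for (int p = 0; p < n; ++p) {
      Vec3 c = cross(e, sub(P[p], P[i0]));
      double d = norm(c) / norm(e);
      if (d > best) { best = d; i2 = p; }
    }
    if (i2 < 0) return false;  // collinear
    Vec3 nn = cross(e, sub(P[i2], P[i0]));
    double ln = norm(nn);
    Vec3 un = {nn.x / ln, nn.y / ln, nn.z / ln};
    int i3 = -1; best = eps;
    for (int p = 0; p < n; ++p) {
      double d = std::fabs(dot(un, sub(P[p], P[i0])));
      if (d > best) { best = d; i3 = p; }
    }
    if (i3 < 0) return false;  // coplanar
    inner = {(P[i0].x + P[i1].x + P[i2].x + P[i3].x) / 4.0,
             (P[i0].y + P[i1].y + P[i2].y + P[i3].y) / 4.0,
             (P[i0].z + P[i1].z + P[i2].z + P[i3].z) / 4.0};
    make_face(i0, i1, i2);
    make_face(i0, i1, i3);
    make_face(i0, i2, i3);
    make_face(i1, i2, i3);
    {
      std::vector<int> all(n);
      for (int p = 0; p < n; ++p) all[p] = p;
      std::vector<Face*> t;
      for (auto& f : faces) t.push_back(&f);
      assign(all, t);
    }
    // iterate: note faces vector may reallocate; work with indices
    for (long guard = 0; guard < 100L * n + 1000; ++guard) {
      int fi = -1;
      for (int q = 0; q < (int)faces.size(); ++q)
        if (faces[q].alive && !faces[q].conflicts.empty()) { fi = q; break; }
      if (fi < 0) return true;  // done
      int p = faces[fi].far_p;
      // visible faces
      std::vector<int> visible;
      for (int q = 0; q < (int)faces.size(); ++q)
        if (faces[q].alive && dist(faces[q], p) > eps) visible.push_back(q);
      // horizon: directed edges of visible faces appearing once
      std::unordered_map<std::uint64_t, int> ecount;
      auto key = [](int a, int b) {
        int lo = std::min(a, b), hi = std::max(a, b);
        return ((std::uint64_t)lo << 32) | (std::uint64_t)hi;
      };
      for (int q : visible)
        for (int s = 0; s < 3; ++s) {
          int a = faces[q].v[s], b = faces[q].v[(s + 1) % 3];
          ecount[key(a, b)]++;
        }
      std::vector<int> orphans;
      for (int q : visible) {
        orphans.insert(orphans.end(), faces[q].conflicts.begin(),
                       faces[q].conflicts.end());
        faces[q].alive = false;
        faces[q].conflicts.clear();
      }
      size_t first_new = faces.size();
      for (int q : visible)
        for (int s = 0; s < 3; ++s) {
          int a = faces[q].v[s], b = faces[q].v[(s + 1) % 3];
          if (ecount[key(a, b)] == 1) make_face(p, a, b);
        }
      std::vector<Face*> targets;
      for (size_t q = first_new; q < faces.size(); ++q) targets.push_back(&faces[q]);
      // drop p itself from orphans
      std::vector<int> keep;
      keep.reserve(orphans.size());
      for (int o : orphans) if (o != p) keep.push_back(o);
      assign(keep, targets);
    }
    return false;  // guard tripped
  }
};

}  // namespace

// Convex hull of a 3D point cloud. Returns facet triangles (1-based indices
// into pts), unit outward plane equations (nx, ny, nz, off), total facet
// area and enclosed volume.
// [[Rcpp::export]]
Rcpp::List cpp_convex_hull(Rcpp::NumericMatrix pts) {
  const int n = pts.nrow();
  if (n < 4) Rcpp::stop("convex hull needs at least 4 points");
  std::vector<Vec3> P(n);
  double lo[3] = {R_PosInf, R_PosInf, R_PosInf};
  double hi[3] = {R_NegInf, R_NegInf, R_NegInf};
  for (int i = 0; i < n; ++i) {
    P[i] = {pts(i, 0), pts(i, 1), pts(i, 2)};
    double c[3] = {P[i].x, P[i].y, P[i].z};
    for (int d = 0; d < 3; ++d) {
      lo[d] = std::min(lo[d], c[d]);
      hi[d] = std::max(hi[d], c[d]);
    }
  }
  double diag = std::sqrt((hi[0] - lo[0]) * (hi[0] - lo[0]) +
                          (hi[1] - lo[1]) * (hi[1] - lo[1]) +
                          (hi[2] - lo[2]) * (hi[2] - lo[2]));
  HullBuilder hb(P, std::max(1e-12, 1e-9 * diag));
  if (!hb.build())
    Rcpp::stop("degenerate point set: convex hull is not three-dimensional");
  int nf = 0;
  for (auto& f : hb.faces) if (f.alive) ++nf;
  Rcpp::IntegerMatrix tri(nf, 3);
  Rcpp::NumericMatrix planes(nf, 4);
  double area = 0.0, vol = 0.0;
  Vec3 c0 = hb.inner;
  int r = 0;
  for (auto& f : hb.faces) {
    if (!f.alive) continue;
    tri(r, 0) = f.v[0] + 1; tri(r, 1) = f.v[1] + 1; tri(r, 2) = f.v[2] + 1;
    planes(r, 0) = f.n.x; planes(r, 1) = f.n.y; planes(r, 2) = f.n.z;
    planes(r, 3) = f.off;
    Vec3 a = sub(P[f.v[1]], P[f.v[0]]), b = sub(P[f.v[2]], P[f.v[0]]);
    double ta = 0.5 * norm(cross(a, b));
    area += ta;
    vol += ta * (dot(f.n, sub(P[f.v[0]], c0))) / 3.0;
    ++r;
  }
  return Rcpp::List::create(Rcpp::Named("triangles") = tri,
                            Rcpp::Named("planes") = planes,
                            Rcpp::Named("area") = area,
                            Rcpp::Named("volume") = vol);
}

// Voxelize a convex polytope given by outward unit plane equations: voxel
// centres with dot(n, x) <= off + pad for every plane. Per (y,z) row the
// feasible x set is an interval, so cost is n_rows * n_planes.
// [[Rcpp::export]]
Rcpp::LogicalVector cpp_hull_mask(Rcpp::NumericMatrix planes,
                                  Rcpp::IntegerVector dims,
                                  Rcpp::NumericVector spacing, double pad) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int np = planes.nrow();
  Rcpp::LogicalVector mask((R_xlen_t)nx * ny * nz);
  mask.attr("dim") = dims;
  for (int k = 0; k < nz; ++k) {
    double z = (k + 0.5) * spacing[2];
    for (int j = 0; j < ny; ++j) {
      double y = (j + 0.5) * spacing[1];
      double xlo = 0.5 * spacing[0];
      double xhi = (nx - 0.5) * spacing[0];
      bool feasible = true;
      for (int p = 0; p < np && feasible; ++p) {
        double a = planes(p, 0), b = planes(p, 1), c = planes(p, 2);
        double rhs = planes(p, 3) + pad - b * y - c * z;
        if (std::fabs(a) < 1e-12) {
          if (rhs < 0) feasible = false;
        } else if (a > 0) {
          xhi = std::min(xhi, rhs / a);
        } else {
          xlo = std::max(xlo, rhs / a);
        }
      }
      if (!feasible || xlo > xhi) continue;
      int ilo = (int)std::ceil(xlo / spacing[0] - 0.5);
      int ihi = (int)std::floor(xhi / spacing[0] - 0.5);
      ilo = std::max(0, ilo); ihi = std::min(nx - 1, ihi);
      for (int i = ilo; i <= ihi; ++i) mask[vox_idx(i, j, k, nx, ny)] = true;
    }
  }
  return mask;
}
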