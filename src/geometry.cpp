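// Mesh geometry kernels: closest point on a triangulated surface (uniform-grid
// accelerated), point-in-mesh parity tests, and parity-fill voxelization.
// Coordinates are world millimetres throughout; faces are 0-based on entry.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
#include <limits>
using namespace Rcpp;

namespace {

struct Vec3 {
  double x, y, z;
};
inline Vec3 v3(double x, double y, double z) { Vec3 v = {x, y, z}; return v; }
inline Vec3 operator-(const Vec3& a, const Vec3& b) { return v3(a.x - b.x, a.y - b.y, a.z - b.z); }
inline Vec3 operator+(const Vec3& a, const Vec3& b) { return v3(a.x + b.x, a.y + b.y, a.z + b.z); }
inline Vec3 operator*(double s, const Vec3& a) { return v3(s * a.x, s * a.y, s * a.z); }
inline double dot(const Vec3& a, const Vec3& b) { return a.x * b.x + a.y * b.y + a.z * b.z; }
inline Vec3 cross(const Vec3& a, const Vec3& b) {
  return v3(a.y * b.z - a.z * b.y, a.z * b.x - a.x * b.z, a.x * b.y - a.y * b.x);
}
inline double norm2(const Vec3& a) { return dot(a, a); }

// Closest point on triangle (a,b,c) to p; Ericson, Real-Time Collision Detection.
Vec3 closest_on_triangle(const Vec3& p, const Vec3& a, const Vec3& b, const Vec3& c) {
  Vec3 ab = b - a, ac = c - a, ap = p - a;
  double d1 = dot(ab, ap), d2 = dot(ac, ap);
  if (d1 <= 0.0 && d2 <= 0.0) return a;
  Vec3 bp = p - b;
  double d3 = dot(ab, bp), d4 = dot(ac, bp);
  if (d3 >= 0.0 && d4 <= d3) return b;
  double vc = d1 * d4 - d3 * d2;
  if (vc <= 0.0 && d1 >= 0.0 && d3 <= 0.0) {
    double v = d1 / (d1 - d3);
    return a + v * ab;
  }
  Vec3 cp = p - c;
  double d5 = dot(ab, cp), d6 = dot(ac, cp);
  if (d6 >= 0.0 && d5 <= d6) return c;
  double vb = d5 * d2 - d1 * d6;
  if (vb <= 0.0 && d2 >= 0.0 && d6 <= 0.0) {
    double w = d2 / (d2 - d6);
    return a + w * ac;
  }
  double va = d3 * d6 - d5 * d4;
  if (va <= 0.0 && (d4 - d3) >= 0.0 && (d5 - d6) >= 0.0) {
    double w = (d4 - d3) / ((d4 - d3) + (d5 - d6));
    return b + w * (c - b);
  }
  double denom = 1.0 / (va + vb + vc);
  double v = vb * denom, w = vc * denom;
  return a + v * ab + w * ac;
}

struct MeshRef {
  const double* V;  // N x 3 column-major
  const int* F;     // M x 3 column-major, 0-based
  int nv, nf;
  Vec3 vert(int i) const { return v3(V[i], V[i + nv], V[i + 2 * nv]); }
  void tri(int t, Vec3& a, Vec3& b, Vec3& c) const {
    a = vert(F[t]); b = vert(F[t + nf]); c = vert(F[t + 2 * nf]);
  }
};

// Uniform grid over triangle bounding boxes for closest-point queries.
struct TriGrid {
  double lo[3], cell[3];
  int n[3];
  std::vector<std::vector<int> > bins;
  std::vector<double> tlo, thi;  // per-tri bbox, 3*nf each

  void build(const MeshRef& m) {
    double hi[3];
    for (int d = 0; d < 3; ++d) { lo[d] = std::numeric_limits<double>::max(); hi[d] = -lo[d]; }
    tlo.resize(3 * m.nf); thi.resize(3 * m.nf);
    double mean_ext = 0.0;
    for (int t = 0; t < m.nf; ++t) {
      Vec3 a, b, c; m.tri(t, a, b, c);
      double bl[3] = {std::min(a.x, std::min(b.x, c.x)), std::min(a.y, std::min(b.y, c.y)),
                      std::min(a.z, std::min(b.z, c.z))};
      double bh[3] = {std::max(a.x, std::max(b.x, c.x)), std::max(a.y, std::max(b.y, c.y)),
                      std::max(a.z, std::max(b.z, c.z))};
      for (int d = 0; d < 3; ++d) {
        tlo[3 * t + d] = bl[d]; thi[3 * t + d] = bh[d];
        lo[d] = std::min(lo[d], bl[d]); hi[d] = std::max(hi[d], bh[d]);
        mean_ext += (bh[d] - bl[d]);
      }
    }
    mean_ext /= (3.0 * m.nf);
    double target = std::max(mean_ext * 2.0, 1e-6);
    long ncell_cap = 2000000;
    for (int d = 0; d < 3; ++d) {
      double ext = std::max(hi[d] - lo[d], 1e-9);
      n[d] = std::max(1, (int)std::floor(ext / target));
    }
    while ((long)n[0] * n[1] * n[2] > ncell_cap) {
      for (int d = 0; d < 3; ++d) n[d] = std::max(1, n[d] / 2);
    }
    for (int d = 0; d < 3; ++d) {
      double ext = std::max(hi[d] - lo[d], 1e-9);
      cell[d] = ext / n[d] * (1.0 + 1e-12);
    }
    bins.assign((size_t)n[0] * n[1] * n[2], std::vector<int>());
    for (int t = 0; t < m.nf; ++t) {
      int i0[3], i1[3];
      for (int d = 0; d < 3; ++d) {
        i0[d] = clampi((int)std::floor((tlo[3 * t + d] - lo[d]) / cell[d]), 0, n[d] - 1);
        i1[d] = clampi((int)std::floor((thi[3 * t + d] - lo[d]) / cell[d]), 0, n[d] - 1);
      }
      for (int i = i0[0]; i <= i1[0]; ++i)
        for (int j = i0[1]; j <= i1[1]; ++j)
          for (int k = i0[2]; k <= i1[2]; ++k)
            bins[idx(i, j, k)].push_back(t);
    }
  }
  static int clampi(int v, int a, int b) { return v < a ? a : (v > b ? b : v); }
  size_t idx(int i, int j, int k) const { return (size_t)i + (size_t)n[0] * (j + (size_t)n[1] * k); }

  // closest point on mesh to p; returns squared distance, fills cp and face.
  double query(const MeshRef& m, const Vec3& p, Vec3& cp, int& face) const {
    int ci[3];
    for (int d = 0; d < 3; ++d) {
      double pd = d == 0 ? p.x : (d == 1 ? p.y : p.z);
      ci[d] = clampi((int)std::floor((pd - lo[d]) / cell[d]), 0, n[d] - 1);
    }
    double best = std::numeric_limits<double>::max();
    double cmin = std::min(cell[0], std::min(cell[1], cell[2]));
    int max_ring = n[0] + n[1] + n[2] + 2;
    for (int ring = 0; ring < max_ring; ++ring) {
      // once a hit exists, stop when the nearest possible cell in this ring
      // is farther than the current best
      if (best < std::numeric_limits<double>::max()) {
        double dmin = (ring - 1) * cmin;
        if (dmin > 0 && dmin * dmin > best) break;
      }
      bool any_cell = false;
      int ilo = ci[0] - ring, ihi = ci[0] + ring;
      int jlo = ci[1] - ring, jhi = ci[1] + ring;
      int klo = ci[2] - ring, khi = ci[2] + ring;
      for (int i = ilo; i <= ihi; ++i) {
        if (i < 0 || i >= n[0]) continue;
        for (int j = jlo; j <= jhi; ++j) {
          if (j < 0 || j >= n[1]) continue;
          for (int k = klo; k <= khi; ++k) {
            if (k < 0 || k >= n[2]) continue;
            // only the shell of the ring
            if (ring > 0 && std::abs(i - ci[0]) != ring && std::abs(j - ci[1]) != ring &&
                std::abs(k - ci[2]) != ring)
              continue;
            any_cell = true;
            const std::vector<int>& lst = bins[idx(i, j, k)];
            for (size_t q = 0; q < lst.size(); ++q) {
              int t = lst[q];
              // bbox lower-bound reject
              double lb = 0.0;
              const double pd[3] = {p.x, p.y, p.z};
              for (int d = 0; d < 3; ++d) {
                double e = 0.0;
                if (pd[d] < tlo[3 * t + d]) e = tlo[3 * t + d] - pd[d];
                else if (pd[d] > thi[3 * t + d]) e = pd[d] - thi[3 * t + d];
                lb += e * e;
              }
              if (lb >= best) continue;
              Vec3 a, b, c; m.tri(t, a, b, c);
              Vec3 q3 = closest_on_triangle(p, a, b, c);
              double d2 = norm2(p - q3);
              if (d2 < best) { best = d2; cp = q3; face = t; }
            }
          }
        }
      }
      if (!any_cell && ring > 0 && best < std::numeric_limits<double>::max()) break;
    }
    return best;
  }
};

// Ray-triangle intersection (Moller-Trumbore); returns t or NA.
bool ray_tri(const Vec3& o, const Vec3& dir, const Vec3& a, const Vec3& b, const Vec3& c,
             double& tout) {
  const double eps = 1e-12;
  Vec3 e1 = b - a, e2 = c - a;
  Vec3 h = cross(dir, e2);
  double det = dot(e1, h);
  if (std::fabs(det) < eps) return false;
  double inv = 1.0 / det;
  Vec3 s = o - a;
  double u = dot(s, h) * inv;
  if (u < 0.0 || u > 1.0) return false;
  Vec3 qv = cross(s, e1);
  double v = dot(dir, qv) * inv;
  if (v < 0.0 || u + v > 1.0) return false;
  double t = dot(e2, qv) * inv;
  if (t <= eps) return false;
  tout = t;
  return true;
}

}  // namespace

// [[Rcpp::export]]
List cpp_closest_on_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  MeshRef m = {REAL(V), INTEGER(F), V.nrow(), F.nrow()};
  TriGrid grid;
  grid.build(m);
  int np = P.nrow();
  NumericVector dist(np);
  NumericMatrix cp(np, 3);
  IntegerVector face(np);
  for (int i = 0; i < np; ++i) {
    Vec3 p = v3(P(i, 0), P(i, 1), P(i, 2)), q;
    int f = -1;
    double d2 = grid.query(m, p, q, f);
    dist[i] = std::sqrt(d2);
    cp(i, 0) = q.x; cp(i, 1) = q.y; cp(i, 2) = q.z;
    face[i] = f + 1;
  }
  return List::create(_["dist"] = dist, _["point"] = cp, _["face"] = face);
}

// [[Rcpp::export]]
LogicalVector cpp_points_in_mesh(NumericMatrix P, NumericMatrix V, IntegerMatrix F) {
  MeshRef m = {REAL(V), INTEGER(F), V.nrow(), F.nrow()};
  int np = P.nrow();
  LogicalVector inside(np);
  // slightly irrational direction avoids edge/vertex degeneracies for
  // generic meshes; a second direction is tried if a hit is suspiciously
  // close to an edge (parity robustness)
  Vec3 dirs[3] = {v3(1.0, 1.7320508e-4, 2.2360680e-4),
                  v3(2.2360680e-4, 1.0, 1.7320508e-4),
                  v3(1.41421e-4, 2.64575e-4, 1.0)};
  for (int i = 0; i < np; ++i) {
    Vec3 p = v3(P(i, 0), P(i, 1), P(i, 2));
    int votes = 0;
    for (int d = 0; d < 2; ++d) {
      int nhit = 0;
      double t;
      for (int tIdx = 0; tIdx < m.nf; ++tIdx) {
        Vec3 a, b, c;
        m.tri(tIdx, a, b, c);
        if (ray_tri(p, dirs[d], a, b, c, t)) ++nhit;
      }
      votes += (nhit % 2);
    }
    if (votes == 1) {  // disagreement: use third direction as tie-break
      int nhit = 0; double t;
      for (int tIdx = 0; tIdx < m.nf; ++tIdx) {
        Vec3 a, b, c;
        m.tri(tIdx, a, b, c);
        if (ray_tri(p, dirs[2], a, b, c, t)) ++nhit;
      }
      votes += (nhit % 2);
    }
    inside[i] = votes >= 2;
  }
  return inside;
}

// Parity-fill voxelization: cast a ray along +x through every voxel-column
// centre, collect triangle crossings, fill between successive pairs.
// origin is the world position of voxel (0,0,0); voxel centres at
// origin + spacing * index.
// [[Rcpp::export]]
NumericVector cpp_voxelize(NumericMatrix V, IntegerMatrix F, NumericVector origin,
                           NumericVector spacing, IntegerVector dims) {
  MeshRef m = {REAL(V), INTEGER(F), V.nrow(), F.nrow()};
  int nx = dims[0], ny = dims[1], nz = dims[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];
  double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  // tiny irrational offsets of the column sample avoid edge-on degeneracy
  const double ey = 2.9429e-6 * sy, ez = 4.1421e-6 * sz;
  std::vector<std::vector<float> > cols((size_t)ny * nz);
  for (int t = 0; t < m.nf; ++t) {
    Vec3 a, b, c;
    m.tri(t, a, b, c);
    double ylo = std::min(a.y, std::min(b.y, c.y)), yhi = std::max(a.y, std::max(b.y, c.y));
    double zlo = std::min(a.z, std::min(b.z, c.z)), zhi = std::max(a.z, std::max(b.z, c.z));
    int j0 = std::max(0, (int)std::ceil((ylo - oy - ey) / sy));
    int j1 = std::min(ny - 1, (int)std::floor((yhi - oy - ey) / sy));
    int k0 = std::max(0, (int)std::ceil((zlo - oz - ez) / sz));
    int k1 = std::min(nz - 1, (int)std::floor((zhi - oz - ez) / sz));
    if (j0 > j1 || k0 > k1) continue;
    // plane: n . x = d
    Vec3 nrm = cross(b - a, c - a);
    if (std::fabs(nrm.x) < 1e-14) continue;  // parallel to ray; neighbours cover it
    double dpl = dot(nrm, a);
    // 2D (y,z) edge functions for point-in-triangle
    double ay = a.y, az = a.z, by = b.y, bz = b.z, cy = c.y, cz = c.z;
    double area2 = (by - ay) * (cz - az) - (bz - az) * (cy - ay);
    if (std::fabs(area2) < 1e-16) continue;
    for (int j = j0; j <= j1; ++j) {
      double y = oy + sy * j + ey;
      for (int k = k0; k <= k1; ++k) {
        double z = oz + sz * k + ez;
        double w0 = (by - y) * (cz - z) - (bz - z) * (cy - y);
        double w1 = (cy - y) * (az - z) - (cz - z) * (ay - y);
        double w2 = (ay - y) * (bz - z) - (az - z) * (by - y);
        bool pos = area2 > 0;
        bool in = pos ? (w0 >= 0 && w1 >= 0 && w2 >= 0) : (w0 <= 0 && w1 <= 0 && w2 <= 0);
        if (!in) continue;
        double x = (dpl - nrm.y * y - nrm.z * z) / nrm.x;
        cols[(size_t)j + (size_t)ny * k].push_back((float)x);
      }
    }
  }
  NumericVector out((R_xlen_t)nx * ny * nz);
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      std::vector<float>& xs = cols[(size_t)j + (size_t)ny * k];
      if (xs.empty()) continue;
      std::sort(xs.begin(), xs.end());
      // drop near-duplicate crossings (shared-edge double hits)
      std::vector<float> u;
      for (size_t q = 0; q < xs.size(); ++q) {
        if (u.empty() || xs[q] - u.back() > 1e-6) u.push_back(xs[q]);
        else u.pop_back();  // coincident pair: tangential touch, cancel
      }
      size_t npair = u.size() / 2;
      for (size_t q = 0; q < npair; ++q) {
        double x0 = u[2 * q], x1 = u[2 * q + 1];
        // half-open [x0, x1): voxel centres landing exactly on the exit
        // face are not counted twice across abutting solids
        int i0 = std::max(0, (int)std::ceil((x0 - ox) / sx - 1e-9));
        int i1 = std::min(nx - 1, (int)std::floor((x1 - ox) / sx - 1e-9));
        for (int i = i0; i <= i1; ++i)
          out[(R_xlen_t)i + (R_xlen_t)nx * (j + (R_xlen_t)ny * k)] = 1.0;
      }
    }
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}
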