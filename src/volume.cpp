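// Volume kernels: trilinear sampling, grid resampling, affine warps,
// separable box-Gaussian smoothing, SSD + analytic gradient for affine
// registration. Volumes are column-major [nx, ny, nz]; the world position
// of voxel (i,j,k) (0-based) is origin + spacing * (i,j,k).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

// trilinear sample at continuous 0-based index coordinates; outside -> 0
inline double tri_at(const double* v, int nx, int ny, int nz, double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) return 0.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) --i0;
  if (j0 == ny - 1) --j0;
  if (k0 == nz - 1) --k0;
  if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  long s0 = 1, s1 = nx, s2 = (long)nx * ny;
  const double* p = v + i0 * s0 + j0 * s1 + k0 * s2;
  int di = nx > 1 ? 1 : 0, dj = ny > 1 ? 1 : 0, dk = nz > 1 ? 1 : 0;
  double c00 = p[0] * (1 - fx) + p[di * s0] * fx;
  double c10 = p[dj * s1] * (1 - fx) + p[di * s0 + dj * s1] * fx;
  double c01 = p[dk * s2] * (1 - fx) + p[di * s0 + dk * s2] * fx;
  double c11 = p[dj * s1 + dk * s2] * (1 - fx) + p[di * s0 + dj * s1 + dk * s2] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

// one box-filter pass of radius r along a given stride, in place via buffer
void box_pass(std::vector<double>& a, int nx, int ny, int nz, int axis, int r) {
  if (r <= 0) return;
  int n[3] = {nx, ny, nz};
  long stride[3] = {1, nx, (long)nx * ny};
  int len = n[axis];
  long s = stride[axis];
  std::vector<double> line(len);
  int o1 = (axis == 0) ? 1 : 0, o2 = (axis == 2) ? 1 : 2;
  for (int b = 0; b < n[o2]; ++b) {
    for (int a2 = 0; a2 < n[o1]; ++a2) {
      long base = (long)a2 * stride[o1] + (long)b * stride[o2];
      double acc = 0.0;
      int w0 = -r - 1, w1 = r;  // window (w0, w1]
      // prime window for index 0
      for (int q = 0; q <= std::min(r, len - 1); ++q) acc += a[base + q * s];
      int cnt = std::min(r, len - 1) + 1;
      for (int i = 0; i < len; ++i) {
        line[i] = acc / cnt;
        int add = i + r + 1, drop = i - r;
        if (add < len) { acc += a[base + add * s]; ++cnt; }
        if (drop >= 0) { acc -= a[base + drop * s]; --cnt; }
      }
      for (int i = 0; i < len; ++i) a[base + i * s] = line[i];
      (void)w0; (void)w1;
    }
  }
}

void smooth3_inplace(std::vector<double>& a, int nx, int ny, int nz,
                     double sx, double sy, double sz) {
  double sig[3] = {sx, sy, sz};
  int n[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    if (sig[axis] < 0.3 || n[axis] < 2) continue;
    // 3 iterated box passes approximate a Gaussian; box radius from sigma
    double w = std::sqrt(12.0 * sig[axis] * sig[axis] / 3.0 + 1.0);
    int r = std::max(1, (int)std::floor((w - 1.0) / 2.0 + 0.5));
    for (int pass = 0; pass < 3; ++pass) box_pass(a, nx, ny, nz, axis, r);
  }
}

}  // namespace

// [[Rcpp::export]]
NumericVector cpp_interp_volume(NumericVector vol, IntegerVector dims, NumericVector origin,
                                NumericVector spacing, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int np = pts.nrow();
  NumericVector out(np);
  const double* v = REAL(vol);
  for (int q = 0; q < np; ++q) {
    double x = (pts(q, 0) - origin[0]) / spacing[0];
    double y = (pts(q, 1) - origin[1]) / spacing[1];
    double z = (pts(q, 2) - origin[2]) / spacing[2];
    out[q] = tri_at(v, nx, ny, nz, x, y, z);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resample(NumericVector vol, IntegerVector dims, NumericVector origin,
                           NumericVector spacing, IntegerVector ndims, NumericVector norigin,
                           NumericVector nspacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = ndims[0], my = ndims[1], mz = ndims[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  const double* v = REAL(vol);
  double* o = REAL(out);
  for (int k = 0; k < mz; ++k) {
    double wz = norigin[2] + nspacing[2] * k;
    double z = (wz - origin[2]) / spacing[2];
    for (int j = 0; j < my; ++j) {
      double wy = norigin[1] + nspacing[1] * j;
      double y = (wy - origin[1]) / spacing[1];
      long row = (long)mx * (j + (long)my * k);
      for (int i = 0; i < mx; ++i) {
        double wx = norigin[0] + nspacing[0] * i;
        double x = (wx - origin[0]) / spacing[0];
        o[row + i] = tri_at(v, nx, ny, nz, x, y, z);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  return out;
}

// out(x) = vol(L x + t), evaluated on the output grid (world coords)
// [[Rcpp::export]]
NumericVector cpp_warp_affine(NumericVector vol, IntegerVector dims, NumericVector origin,
                              NumericVector spacing, IntegerVector odims, NumericVector oorigin,
                              NumericVector ospacing, NumericMatrix L, NumericVector t) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  int mx = odims[0], my = odims[1], mz = odims[2];
  NumericVector out((R_xlen_t)mx * my * mz);
  const double* v = REAL(vol);
  double* o = REAL(out);
  for (int k = 0; k < mz; ++k) {
    double wz = oorigin[2] + ospacing[2] * k;
    for (int j = 0; j < my; ++j) {
      double wy = oorigin[1] + ospacing[1] * j;
      long row = (long)mx * (j + (long)my * k);
      for (int i = 0; i < mx; ++i) {
        double wx = oorigin[0] + ospacing[0] * i;
        double px = L(0, 0) * wx + L(0, 1) * wy + L(0, 2) * wz + t[0];
        double py = L(1, 0) * wx + L(1, 1) * wy + L(1, 2) * wz + t[1];
        double pz = L(2, 0) * wx + L(2, 1) * wy + L(2, 2) * wz + t[2];
        o[row + i] = tri_at(v, nx, ny, nz, (px - origin[0]) / spacing[0],
                            (py - origin[1]) / spacing[1], (pz - origin[2]) / spacing[2]);
      }
    }
  }
  out.attr("dim") = IntegerVector::create(mx, my, mz);
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_smooth3(NumericVector vol, IntegerVector dims, NumericVector sigma_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<double> a(REAL(vol), REAL(vol) + (size_t)nx * ny * nz);
  smooth3_inplace(a, nx, ny, nz, sigma_vox[0], sigma_vox[1], sigma_vox[2]);
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::copy(a.begin(), a.end(), REAL(out));
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// SSD and analytic gradient for the affine map y = L x + t (fixed -> moving
// world coords). gradM holds the three spatial-derivative volumes of the
// moving image (per mm), sampled at y. Returns ssd, grad (12: L row-major
// then t), and the number of contributing voxels.
// [[Rcpp::export]]
List cpp_affine_ssd_grad(NumericVector fixedv, IntegerVector fdims, NumericVector forigin,
                         NumericVector fspacing, NumericVector movv, NumericVector gmx,
                         NumericVector gmy, NumericVector gmz, IntegerVector mdims,
                         NumericVector morigin, NumericVector mspacing, NumericMatrix L,
                         NumericVector t, bool want_grad) {
  int fx = fdims[0], fy = fdims[1], fz = fdims[2];
  int mx = mdims[0], my = mdims[1], mz = mdims[2];
  const double* F = REAL(fixedv);
  const double* M = REAL(movv);
  const double* Gx = REAL(gmx);
  const double* Gy = REAL(gmy);
  const double* Gz = REAL(gmz);
  double ssd = 0.0;
  std::vector<double> g(12, 0.0);
  long nvox = 0;
  for (int k = 0; k < fz; ++k) {
    double wz = forigin[2] + fspacing[2] * k;
    for (int j = 0; j < fy; ++j) {
      double wy = forigin[1] + fspacing[1] * j;
      long row = (long)fx * (j + (long)fy * k);
      for (int i = 0; i < fx; ++i) {
        double f = F[row + i];
        double wx = forigin[0] + fspacing[0] * i;
        double px = L(0, 0) * wx + L(0, 1) * wy + L(0, 2) * wz + t[0];
        double py = L(1, 0) * wx + L(1, 1) * wy + L(1, 2) * wz + t[1];
        double pz = L(2, 0) * wx + L(2, 1) * wy + L(2, 2) * wz + t[2];
        double ix = (px - morigin[0]) / mspacing[0];
        double iy = (py - morigin[1]) / mspacing[1];
        double iz = (pz - morigin[2]) / mspacing[2];
        double m = tri_at(M, mx, my, mz, ix, iy, iz);
        if (f == 0.0 && m == 0.0) continue;
        double d = m - f;
        ssd += d * d;
        ++nvox;
        if (want_grad) {
          double gx = tri_at(Gx, mx, my, mz, ix, iy, iz);
          double gy = tri_at(Gy, mx, my, mz, ix, iy, iz);
          double gz = tri_at(Gz, mx, my, mz, ix, iy, iz);
          double c = 2.0 * d;
          g[0] += c * gx * wx; g[1] += c * gx * wy; g[2] += c * gx * wz;
          g[3] += c * gy * wx; g[4] += c * gy * wy; g[5] += c * gy * wz;
          g[6] += c * gz * wx; g[7] += c * gz * wy; g[8] += c * gz * wz;
          g[9] += c * gx; g[10] += c * gy; g[11] += c * gz;
        }
      }
    }
  }
  return List::create(_["ssd"] = ssd, _["grad"] = NumericVector(g.begin(), g.end()),
                      _["n"] = (double)nvox);
}

// ---- exact Euclidean distance transform (Felzenszwalb & Huttenlocher) ----
namespace {

// 1D squared-distance lower envelope; f/d length n, sample step `step`
void dt1d(const double* f, double* d, int n, double step, std::vector<int>& v,
          std::vector<double>& z) {
  if ((int)v.size() < n) { v.resize(n); z.resize(n + 1); }
  int k = 0;
  v[0] = 0;
  z[0] = -1e30;
  z[1] = 1e30;
  for (int q = 1; q < n; ++q) {
    double xq = q * step;
    double s;
    while (true) {
      double xv = v[k] * step;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = 1e30;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double xq = q * step;
    while (z[k + 1] < xq) ++k;
    double xv = v[k] * step;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

}  // namespace

// depth (mm) of each inside voxel to the nearest outside voxel centre;
// outside voxels get 0. `inside` is the binary occupancy.
// [[Rcpp::export]]
NumericVector cpp_interior_depth(NumericVector occ, IntegerVector dims,
                                 NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  const double* O = REAL(occ);
  std::vector<double> g(n);
  const double INF = 1e30;
  for (long q = 0; q < n; ++q) g[q] = O[q] > 0.5 ? INF : 0.0;
  std::vector<int> venv;
  std::vector<double> zenv;
  std::vector<double> line(std::max(nx, std::max(ny, nz)));
  std::vector<double> dist(line.size());
  // x pass
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      long base = (long)nx * (j + (long)ny * k);
      dt1d(&g[base], &dist[0], nx, spacing[0], venv, zenv);
      std::copy(dist.begin(), dist.begin() + nx, g.begin() + base);
    }
  // y pass
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) line[j] = g[(long)i + (long)nx * (j + (long)ny * k)];
      dt1d(&line[0], &dist[0], ny, spacing[1], venv, zenv);
      for (int j = 0; j < ny; ++j) g[(long)i + (long)nx * (j + (long)ny * k)] = dist[j];
    }
  // z pass
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) line[k] = g[(long)i + (long)nx * (j + (long)ny * k)];
      dt1d(&line[0], &dist[0], nz, spacing[2], venv, zenv);
      for (int k = 0; k < nz; ++k) g[(long)i + (long)nx * (j + (long)ny * k)] = dist[k];
    }
  NumericVector out(n);
  for (long q = 0; q < n; ++q) out[q] = g[q] >= 1e29 ? 0.0 : std::sqrt(g[q]);
  out.attr("dim") = dims;
  return out;
}
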