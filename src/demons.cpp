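// Demons-style deformable registration loop, displacement-field utilities
// (warping, inversion, composition, Jacobian monitoring). A displacement
// field u is stored as a [nx,ny,nz,3] array (mm, world axes) on the fixed
// grid; the deformation acts as x -> x + u(x).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

template <typename T>
inline double tri_at(const T* v, int nx, int ny, int nz, double x, double y, double z) {
  if (x < 0 || y < 0 || z < 0 || x > nx - 1 || y > ny - 1 || z > nz - 1) return 0.0;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) --i0;
  if (j0 == ny - 1) --j0;
  if (k0 == nz - 1) --k0;
  if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  long s1 = nx, s2 = (long)nx * ny;
  const T* p = v + i0 + j0 * s1 + k0 * s2;
  int di = nx > 1 ? 1 : 0, dj = ny > 1 ? 1 : 0, dk = nz > 1 ? 1 : 0;
  double c00 = p[0] * (1 - fx) + p[di] * fx;
  double c10 = p[dj * s1] * (1 - fx) + p[di + dj * s1] * fx;
  double c01 = p[dk * s2] * (1 - fx) + p[di + dk * s2] * fx;
  double c11 = p[dj * s1 + dk * s2] * (1 - fx) + p[di + dj * s1 + dk * s2] * fx;
  double c0 = c00 * (1 - fy) + c10 * fy;
  double c1 = c01 * (1 - fy) + c11 * fy;
  return c0 * (1 - fz) + c1 * fz;
}

template <typename T>
inline double tri_clamp(const T* v, int nx, int ny, int nz, double x, double y, double z) {
  if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
  if (x > nx - 1) x = nx - 1;
  if (y > ny - 1) y = ny - 1;
  if (z > nz - 1) z = nz - 1;
  return tri_at(v, nx, ny, nz, x, y, z);
}

// clamped trilinear sample of all three components of a field at once
template <typename T>
inline void tri_clamp3(const T* u, long n, int nx, int ny, int nz, double x, double y,
                       double z, double out[3]) {
  if (x < 0) x = 0; if (y < 0) y = 0; if (z < 0) z = 0;
  if (x > nx - 1) x = nx - 1;
  if (y > ny - 1) y = ny - 1;
  if (z > nz - 1) z = nz - 1;
  int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
  if (i0 == nx - 1) --i0;
  if (j0 == ny - 1) --j0;
  if (k0 == nz - 1) --k0;
  if (nx == 1) i0 = 0; if (ny == 1) j0 = 0; if (nz == 1) k0 = 0;
  double fx = x - i0, fy = y - j0, fz = z - k0;
  long s1 = nx, s2 = (long)nx * ny;
  int di = nx > 1 ? 1 : 0, dj = ny > 1 ? 1 : 0, dk = nz > 1 ? 1 : 0;
  double w000 = (1 - fx) * (1 - fy) * (1 - fz), w100 = fx * (1 - fy) * (1 - fz);
  double w010 = (1 - fx) * fy * (1 - fz), w110 = fx * fy * (1 - fz);
  double w001 = (1 - fx) * (1 - fy) * fz, w101 = fx * (1 - fy) * fz;
  double w011 = (1 - fx) * fy * fz, w111 = fx * fy * fz;
  long base = i0 + j0 * s1 + k0 * s2;
  for (int c = 0; c < 3; ++c) {
    const T* p = u + c * n + base;
    out[c] = w000 * p[0] + w100 * p[di] + w010 * p[dj * s1] + w110 * p[di + dj * s1] +
             w001 * p[dk * s2] + w101 * p[di + dk * s2] + w011 * p[dj * s1 + dk * s2] +
             w111 * p[di + dj * s1 + dk * s2];
  }
}

// ---- cache-friendly separable box filtering ----
// x-axis: running sum along contiguous rows
template <typename T>
void box_x(std::vector<T>& a, std::vector<T>& buf, int nx, int ny, int nz, int r) {
  if (r <= 0 || nx < 2) return;
  for (long line = 0; line < (long)ny * nz; ++line) {
    T* p = &a[line * nx];
    bool nonzero = false;
    for (int i = 0; i < nx; ++i) {
      if (p[i] != (T)0) { nonzero = true; break; }
    }
    if (!nonzero) continue;
    double acc = 0.0;
    int cnt = std::min(r, nx - 1) + 1;
    for (int q = 0; q <= std::min(r, nx - 1); ++q) acc += p[q];
    for (int i = 0; i < nx; ++i) {
      buf[i] = acc / cnt;
      int add = i + r + 1, drop = i - r;
      if (add < nx) { acc += p[add]; ++cnt; }
      if (drop >= 0) { acc -= p[drop]; --cnt; }
    }
    std::copy(buf.begin(), buf.begin() + nx, p);
  }
}

// y-axis: per z-slice, slide a row accumulator over j (contiguous row ops)
template <typename T>
void box_y(std::vector<T>& a, std::vector<double>& acc, std::vector<T>& out,
           int nx, int ny, int nz, int r) {
  if (r <= 0 || ny < 2) return;
  long slice = (long)nx * ny;
  for (int k = 0; k < nz; ++k) {
    T* s = &a[k * slice];
    std::fill(acc.begin(), acc.begin() + nx, 0.0);
    int jmax = std::min(r, ny - 1);
    for (int j = 0; j <= jmax; ++j) {
      const T* row = s + (long)j * nx;
      for (int i = 0; i < nx; ++i) acc[i] += row[i];
    }
    int cnt = jmax + 1;
    for (int j = 0; j < ny; ++j) {
      double inv = 1.0 / cnt;
      T* orow = &out[(long)j * nx];
      for (int i = 0; i < nx; ++i) orow[i] = acc[i] * inv;
      int add = j + r + 1, drop = j - r;
      if (add < ny) {
        const T* row = s + (long)add * nx;
        for (int i = 0; i < nx; ++i) acc[i] += row[i];
        ++cnt;
      }
      if (drop >= 0) {
        const T* row = s + (long)drop * nx;
        for (int i = 0; i < nx; ++i) acc[i] -= row[i];
        --cnt;
      }
    }
    std::copy(out.begin(), out.begin() + slice, s);
  }
}

// z-axis: slide a plane accumulator over k (contiguous slice ops)
template <typename T>
void box_z(std::vector<T>& a, std::vector<double>& acc, std::vector<T>& out,
           int nx, int ny, int nz, int r) {
  if (r <= 0 || nz < 2) return;
  long slice = (long)nx * ny;
  std::fill(acc.begin(), acc.begin() + slice, 0.0);
  int kmax = std::min(r, nz - 1);
  for (int k = 0; k <= kmax; ++k) {
    const T* s = &a[(long)k * slice];
    for (long q = 0; q < slice; ++q) acc[q] += s[q];
  }
  int cnt = kmax + 1;
  for (int k = 0; k < nz; ++k) {
    double inv = 1.0 / cnt;
    T* o = &out[(long)k * slice];
    for (long q = 0; q < slice; ++q) o[q] = acc[q] * inv;
    int add = k + r + 1, drop = k - r;
    if (add < nz) {
      const T* s = &a[(long)add * slice];
      for (long q = 0; q < slice; ++q) acc[q] += s[q];
      ++cnt;
    }
    if (drop >= 0) {
      const T* s = &a[(long)drop * slice];
      for (long q = 0; q < slice; ++q) acc[q] -= s[q];
      --cnt;
    }
  }
  std::copy(out.begin(), out.begin() + (long)nz * slice, a.begin());
}

template <typename T>
struct SmoothWork {
  std::vector<T> rowbuf, out;
  std::vector<double> acc;
  void ensure(int nx, int ny, int nz) {
    long slice = (long)nx * ny;
    if ((long)rowbuf.size() < nx) rowbuf.resize(nx);
    if ((long)acc.size() < slice) acc.resize(slice);
    if ((long)out.size() < (long)nz * slice) out.resize((long)nz * slice);
  }
};

int box_radius(double sigma_vox) {
  double w = std::sqrt(12.0 * sigma_vox * sigma_vox / 2.0 + 1.0);
  return std::max(1, (int)std::floor((w - 1.0) / 2.0 + 0.5));
}

template <typename T>
void smooth_scalar(std::vector<T>& a, SmoothWork<T>& wk, int nx, int ny, int nz,
                   const double* sig_vox) {
  wk.ensure(nx, ny, nz);
  for (int pass = 0; pass < 2; ++pass) {
    if (sig_vox[0] >= 0.3) box_x(a, wk.rowbuf, nx, ny, nz, box_radius(sig_vox[0]));
    if (sig_vox[1] >= 0.3) box_y(a, wk.acc, wk.out, nx, ny, nz, box_radius(sig_vox[1]));
    if (sig_vox[2] >= 0.3) box_z(a, wk.acc, wk.out, nx, ny, nz, box_radius(sig_vox[2]));
  }
}

template <typename T>
void smooth_field(std::vector<T>& u, SmoothWork<T>& wk, int nx, int ny, int nz,
                  const double* sig_vox) {
  long n = (long)nx * ny * nz;
  std::vector<T> comp(n);
  for (int c = 0; c < 3; ++c) {
    std::copy(u.begin() + c * n, u.begin() + (c + 1) * n, comp.begin());
    smooth_scalar(comp, wk, nx, ny, nz, sig_vox);
    std::copy(comp.begin(), comp.end(), u.begin() + c * n);
  }
}

}  // namespace

// Demons iterations on a single resolution level. fixed/moving share the
// grid (dims, spacing); u0 is the initial field in mm. Returns the field,
// the SSD trace, and iterations actually run (early stop on stagnation).
// [[Rcpp::export]]
List cpp_demons(NumericVector fixedv, NumericVector movv, NumericVector u0, IntegerVector dims,
                NumericVector spacing, int iters, double update_sigma_mm, double total_sigma_mm,
                double tol, double step_cap_vox) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  // single-precision working arrays: the loop is memory-bandwidth bound and
  // sub-0.001 mm field precision is far below registration accuracy
  std::vector<float> F(REAL(fixedv), REAL(fixedv) + n);
  std::vector<float> M(REAL(movv), REAL(movv) + n);
  std::vector<float> u(REAL(u0), REAL(u0) + 3 * n);
  std::vector<float> mw(n), f(3 * n);
  SmoothWork<float> wk;
  double usig[3], tsig[3];
  for (int d = 0; d < 3; ++d) {
    usig[d] = update_sigma_mm / spacing[d];
    tsig[d] = total_sigma_mm / spacing[d];
  }
  double mean_sp = (spacing[0] + spacing[1] + spacing[2]) / 3.0;
  double alpha2 = 1.0 / (mean_sp * mean_sp);
  double cap = step_cap_vox * mean_sp;
  // fixed-image gradient (static over iterations): averaged with the
  // warped-moving gradient below, the ESM-style symmetric force
  std::vector<float> gF(3 * n);
  for (int k = 0; k < nz; ++k) {
    int kp = k < nz - 1 ? k + 1 : k, km = k > 0 ? k - 1 : k;
    for (int j = 0; j < ny; ++j) {
      int jp = j < ny - 1 ? j + 1 : j, jm = j > 0 ? j - 1 : j;
      long row = (long)nx * (j + (long)ny * k);
      long rowjp = (long)nx * (jp + (long)ny * k), rowjm = (long)nx * (jm + (long)ny * k);
      long rowkp = (long)nx * (j + (long)ny * kp), rowkm = (long)nx * (j + (long)ny * km);
      double dyinv = 1.0 / ((jp - jm) * spacing[1]);
      double dzinv = 1.0 / ((kp - km) * spacing[2]);
      for (int i = 0; i < nx; ++i) {
        long q = row + i;
        int ip = i < nx - 1 ? i + 1 : i, im = i > 0 ? i - 1 : i;
        gF[q] = (float)((F[row + ip] - F[row + im]) / ((ip - im) * spacing[0]));
        gF[q + n] = (float)((F[rowjp + i] - F[rowjm + i]) * dyinv);
        gF[q + 2 * n] = (float)((F[rowkp + i] - F[rowkm + i]) * dzinv);
      }
    }
  }
  std::vector<double> trace;
  double prev_ssd = -1.0;
  int stall = 0, it_done = 0;
  std::vector<float> best_u;
  double best_ssd = -1.0;
  for (int it = 0; it < iters; ++it) {
    // warped moving + SSD in one pass: mw(x) = M(x + u(x))
    double ssd = 0.0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        long row = (long)nx * (j + (long)ny * k);
        for (int i = 0; i < nx; ++i) {
          long q = row + i;
          double x = i + u[q] / spacing[0];
          double y = j + u[q + n] / spacing[1];
          double z = k + u[q + 2 * n] / spacing[2];
          double m = tri_at(&M[0], nx, ny, nz, x, y, z);
          mw[q] = (float)m;
          double d = m - F[q];
          ssd += d * d;
        }
      }
    trace.push_back(ssd);
    // stagnation is measured against the best SSD seen so far, so an
    // oscillating tail cannot keep resetting the stall counter
    if (best_ssd >= 0) {
      double rel = (best_ssd - ssd) / std::max(best_ssd, 1e-30);
      if (rel < tol) ++stall; else stall = 0;
    }
    if (best_ssd < 0 || ssd < best_ssd) { best_ssd = ssd; best_u = u; }
    if (stall >= 2) { it_done = it; break; }
    prev_ssd = ssd;
    // demons force from the warped moving image gradient
    for (int k = 0; k < nz; ++k) {
      int kp = k < nz - 1 ? k + 1 : k, km = k > 0 ? k - 1 : k;
      for (int j = 0; j < ny; ++j) {
        int jp = j < ny - 1 ? j + 1 : j, jm = j > 0 ? j - 1 : j;
        long row = (long)nx * (j + (long)ny * k);
        long rowjp = (long)nx * (jp + (long)ny * k), rowjm = (long)nx * (jm + (long)ny * k);
        long rowkp = (long)nx * (j + (long)ny * kp), rowkm = (long)nx * (j + (long)ny * km);
        double dyinv = 1.0 / ((jp - jm) * spacing[1]);
        double dzinv = 1.0 / ((kp - km) * spacing[2]);
        for (int i = 0; i < nx; ++i) {
          long q = row + i;
          int ip = i < nx - 1 ? i + 1 : i, im = i > 0 ? i - 1 : i;
          double gx = 0.5 * ((mw[row + ip] - mw[row + im]) / ((ip - im) * spacing[0]) + gF[q]);
          double gy = 0.5 * ((mw[rowjp + i] - mw[rowjm + i]) * dyinv + gF[q + n]);
          double gz = 0.5 * ((mw[rowkp + i] - mw[rowkm + i]) * dzinv + gF[q + 2 * n]);
          double diff = F[q] - mw[q];
          double den = gx * gx + gy * gy + gz * gz + alpha2 * diff * diff;
          double s = den > 1e-12 ? diff / den : 0.0;
          double fxv = s * gx, fyv = s * gy, fzv = s * gz;
          double stepm2 = fxv * fxv + fyv * fyv + fzv * fzv;
          if (stepm2 > cap * cap) {
            double sc = cap / std::sqrt(stepm2);
            fxv *= sc; fyv *= sc; fzv *= sc;
          }
          f[q] = (float)fxv; f[q + n] = (float)fyv; f[q + 2 * n] = (float)fzv;
        }
      }
    }
    smooth_field(f, wk, nx, ny, nz, usig);
    // compose: u_new(x) = f(x) + u(x + f(x))
    std::vector<float> unew(3 * n);
    double uv[3];
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        long row = (long)nx * (j + (long)ny * k);
        for (int i = 0; i < nx; ++i) {
          long q = row + i;
          double x = i + f[q] / spacing[0];
          double y = j + f[q + n] / spacing[1];
          double z = k + f[q + 2 * n] / spacing[2];
          tri_clamp3(&u[0], n, nx, ny, nz, x, y, z, uv);
          unew[q] = f[q] + (float)uv[0];
          unew[q + n] = f[q + n] + (float)uv[1];
          unew[q + 2 * n] = f[q + 2 * n] + (float)uv[2];
        }
      }
    smooth_field(unew, wk, nx, ny, nz, tsig);
    u.swap(unew);
    it_done = it + 1;
  }
  if (best_ssd >= 0 && !best_u.empty()) u = best_u;
  NumericVector uo(3 * n);
  std::copy(u.begin(), u.end(), REAL(uo));
  uo.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return List::create(_["u"] = uo, _["ssd_trace"] = NumericVector(trace.begin(), trace.end()),
                      _["iterations"] = it_done, _["final_ssd"] = best_ssd);
}

// pull-back warp by a field: out(x) = vol(x + u(x)); vol may live on a
// different grid than the field's (which is the output grid).
// [[Rcpp::export]]
NumericVector cpp_warp_by_field(NumericVector vol, IntegerVector vdims, NumericVector vorigin,
                                NumericVector vspacing, NumericVector u, IntegerVector dims,
                                NumericVector origin, NumericVector spacing) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  int vx = vdims[0], vy = vdims[1], vz = vdims[2];
  const double* V = REAL(vol);
  const double* U = REAL(u);
  NumericVector out(n);
  double* O = REAL(out);
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      long row = (long)nx * (j + (long)ny * k);
      for (int i = 0; i < nx; ++i) {
        long q = row + i;
        double wx = origin[0] + spacing[0] * i + U[q];
        double wy = origin[1] + spacing[1] * j + U[q + n];
        double wz = origin[2] + spacing[2] * k + U[q + 2 * n];
        O[q] = tri_at(V, vx, vy, vz, (wx - vorigin[0]) / vspacing[0],
                      (wy - vorigin[1]) / vspacing[1], (wz - vorigin[2]) / vspacing[2]);
      }
    }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}

// sample a displacement field at world points (clamped interpolation)
// [[Rcpp::export]]
NumericMatrix cpp_field_at_points(NumericVector u, IntegerVector dims, NumericVector origin,
                                  NumericVector spacing, NumericMatrix pts) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  const double* U = REAL(u);
  int np = pts.nrow();
  NumericMatrix out(np, 3);
  double uv[3];
  for (int q = 0; q < np; ++q) {
    double x = (pts(q, 0) - origin[0]) / spacing[0];
    double y = (pts(q, 1) - origin[1]) / spacing[1];
    double z = (pts(q, 2) - origin[2]) / spacing[2];
    tri_clamp3(U, n, nx, ny, nz, x, y, z, uv);
    out(q, 0) = uv[0]; out(q, 1) = uv[1]; out(q, 2) = uv[2];
  }
  return out;
}

// fixed-point field inversion: v_{m+1}(x) = -u(x + v_m(x))
// [[Rcpp::export]]
List cpp_invert_field(NumericVector u, IntegerVector dims, NumericVector spacing, int iters,
                      double tol) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  const double* U = REAL(u);
  std::vector<double> v(3 * n, 0.0), vn(3 * n);
  double resid = 0.0;
  double uv[3];
  for (int it = 0; it < iters; ++it) {
    double change = 0.0;
    for (int k = 0; k < nz; ++k)
      for (int j = 0; j < ny; ++j) {
        long row = (long)nx * (j + (long)ny * k);
        for (int i = 0; i < nx; ++i) {
          long q = row + i;
          double x = i + v[q] / spacing[0];
          double y = j + v[q + n] / spacing[1];
          double z = k + v[q + 2 * n] / spacing[2];
          tri_clamp3(U, n, nx, ny, nz, x, y, z, uv);
          vn[q] = -uv[0]; vn[q + n] = -uv[1]; vn[q + 2 * n] = -uv[2];
          double dx = vn[q] - v[q], dy = vn[q + n] - v[q + n], dz = vn[q + 2 * n] - v[q + 2 * n];
          change += std::sqrt(dx * dx + dy * dy + dz * dz);
        }
      }
    v.swap(vn);
    resid = change / n;
    if (resid < tol) break;
  }
  // round-trip residual: mean |u(x + v(x)) + v(x)|
  double rt = 0.0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      long row = (long)nx * (j + (long)ny * k);
      for (int i = 0; i < nx; ++i) {
        long q = row + i;
        double x = i + v[q] / spacing[0];
        double y = j + v[q + n] / spacing[1];
        double z = k + v[q + 2 * n] / spacing[2];
        tri_clamp3(U, n, nx, ny, nz, x, y, z, uv);
        double ex = uv[0] + v[q];
        double ey = uv[1] + v[q + n];
        double ez = uv[2] + v[q + 2 * n];
        rt += std::sqrt(ex * ex + ey * ey + ez * ez);
      }
    }
  rt /= n;
  NumericVector vo(3 * n);
  std::copy(v.begin(), v.end(), REAL(vo));
  vo.attr("dim") = IntegerVector::create(nx, ny, nz, 3);
  return List::create(_["v"] = vo, _["roundtrip_mean_mm"] = rt, _["update_resid"] = resid);
}

// fraction of (masked) voxels where det(I + grad u) > 0
// [[Rcpp::export]]
double cpp_jacobian_positive_frac(NumericVector u, IntegerVector dims, NumericVector spacing,
                                  NumericVector mask) {
  int nx = dims[0], ny = dims[1], nz = dims[2];
  long n = (long)nx * ny * nz;
  const double* U = REAL(u);
  const double* Mk = mask.size() == n ? REAL(mask) : 0;
  long tot = 0, pos = 0;
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        long q = (long)i + (long)nx * (j + (long)ny * k);
        if (Mk && Mk[q] <= 0.05) continue;
        double J[3][3];
        for (int c = 0; c < 3; ++c) {
          const double* uc = U + c * n;
          int ip = i < nx - 1 ? i + 1 : i, im = i > 0 ? i - 1 : i;
          int jp = j < ny - 1 ? j + 1 : j, jm = j > 0 ? j - 1 : j;
          int kp = k < nz - 1 ? k + 1 : k, km = k > 0 ? k - 1 : k;
          J[c][0] = (uc[(long)ip + (long)nx * (j + (long)ny * k)] -
                     uc[(long)im + (long)nx * (j + (long)ny * k)]) / ((ip - im) * spacing[0]);
          J[c][1] = (uc[(long)i + (long)nx * (jp + (long)ny * k)] -
                     uc[(long)i + (long)nx * (jm + (long)ny * k)]) / ((jp - jm) * spacing[1]);
          J[c][2] = (uc[(long)i + (long)nx * (j + (long)ny * kp)] -
                     uc[(long)i + (long)nx * (j + (long)ny * km)]) / ((kp - km) * spacing[2]);
          J[c][c] += 1.0;
        }
        double det = J[0][0] * (J[1][1] * J[2][2] - J[1][2] * J[2][1]) -
                     J[0][1] * (J[1][0] * J[2][2] - J[1][2] * J[2][0]) +
                     J[0][2] * (J[1][0] * J[2][1] - J[1][1] * J[2][0]);
        ++tot;
        if (det > 0) ++pos;
      }
  return tot > 0 ? (double)pos / tot : 1.0;
}
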