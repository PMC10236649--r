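// Iso-surface extraction by marching tetrahedra on a regular grid.
// Each cube is split into 6 tetrahedra sharing the main diagonal, which
// makes face diagonals consistent between neighbouring cubes and yields a
// closed, consistently oriented surface for data that vanishes at the
// boundary. Vertices are deduplicated per grid edge.
#include <Rcpp.h>
#include <vector>
#include <map>
#include <cmath>
using namespace Rcpp;

namespace {

struct EdgeKey {
  long a, b;
  bool operator<(const EdgeKey& o) const { return a < o.a || (a == o.a && b < o.b); }
};

struct MTState {
  std::map<EdgeKey, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
  const double* val;
  int nx, ny, nz;
  double ox, oy, oz, sx, sy, sz, iso;

  long gid(int i, int j, int k) const { return (long)i + (long)nx * (j + (long)ny * k); }
  double v(long g) const {
    double x = val[g];
    return x == iso ? iso + 1e-12 : x;  // avoid exact-iso degeneracy
  }
  void world(long g, double& x, double& y, double& z) const {
    long i = g % nx, j = (g / nx) % ny, k = g / ((long)nx * ny);
    x = ox + sx * i; y = oy + sy * j; z = oz + sz * k;
  }
  int edge_pt(long ga, long gb) {
    EdgeKey key = {std::min(ga, gb), std::max(ga, gb)};
    std::map<EdgeKey, int>::iterator it = edge_vertex.find(key);
    if (it != edge_vertex.end()) return it->second;
    double va = v(ga), vb = v(gb);
    double t = (iso - va) / (vb - va);
    if (t < 0) t = 0; if (t > 1) t = 1;
    double ax, ay, az, bx, by, bz;
    world(ga, ax, ay, az); world(gb, bx, by, bz);
    int id = (int)vx.size();
    vx.push_back(ax + t * (bx - ax));
    vy.push_back(ay + t * (by - ay));
    vz.push_back(az + t * (bz - az));
    edge_vertex[key] = id;
    return id;
  }
  void emit(int a, int b, int c) {
    if (a == b || b == c || a == c) return;
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  }
  // one tetrahedron with corners (grid ids) p0..p3; orientation given by
  // the sign of the tet volume so triangles face away from higher values
  void do_tet(long p0, long p1, long p2, long p3) {
    double d0 = v(p0) - iso, d1 = v(p1) - iso, d2 = v(p2) - iso, d3 = v(p3) - iso;
    int code = (d0 > 0) | ((d1 > 0) << 1) | ((d2 > 0) << 2) | ((d3 > 0) << 3);
    if (code == 0 || code == 15) return;
    long p[4] = {p0, p1, p2, p3};
    // reduce to: exactly which corners are inside (>iso)
    int in[4], nin = 0, out[4], nout = 0;
    double dv[4] = {d0, d1, d2, d3};
    for (int q = 0; q < 4; ++q) {
      if (dv[q] > 0) in[nin++] = q; else out[nout++] = q;
    }
    if (nin == 1) {
      int a = in[0];
      int o0 = out[0], o1 = out[1], o2 = out[2];
      int e0 = edge_pt(p[a], p[o0]);
      int e1 = edge_pt(p[a], p[o1]);
      int e2 = edge_pt(p[a], p[o2]);
      orient_emit(e0, e1, e2, p[a], true);
    } else if (nin == 3) {
      int a = out[0];
      int i0 = in[0], i1 = in[1], i2 = in[2];
      int e0 = edge_pt(p[a], p[i0]);
      int e1 = edge_pt(p[a], p[i1]);
      int e2 = edge_pt(p[a], p[i2]);
      orient_emit(e0, e1, e2, p[a], false);
    } else {  // 2 in, 2 out -> quad
      int a = in[0], b = in[1], c = out[0], d = out[1];
      int eac = edge_pt(p[a], p[c]);
      int ead = edge_pt(p[a], p[d]);
      int ebc = edge_pt(p[b], p[c]);
      int ebd = edge_pt(p[b], p[d]);
      orient_emit(eac, ead, ebd, p[a], true);
      orient_emit(eac, ebd, ebc, p[a], true);
    }
  }
  // orient triangle so its normal points from inside (value>iso) to outside
  void orient_emit(int e0, int e1, int e2, long inside_gid, bool inside_ref) {
    double ix, iy, iz;
    world(inside_gid, ix, iy, iz);
    double ax = vx[e0], ay = vy[e0], az = vz[e0];
    double ux = vx[e1] - ax, uy = vy[e1] - ay, uz = vz[e1] - az;
    double wx = vx[e2] - ax, wy = vy[e2] - ay, wz = vz[e2] - az;
    double nx_ = uy * wz - uz * wy, ny_ = uz * wx - ux * wz, nz_ = ux * wy - uy * wx;
    double px = ix - ax, py = iy - ay, pz = iz - az;
    double s = nx_ * px + ny_ * py + nz_ * pz;
    bool flip = inside_ref ? (s > 0) : (s < 0);
    if (flip) emit(e0, e2, e1); else emit(e0, e1, e2);
  }
};

}  // namespace

// [[Rcpp::export]]
List cpp_marching_tets(NumericVector values, IntegerVector dims, NumericVector origin,
                       NumericVector spacing, double iso) {
  MTState st;
  st.val = REAL(values);
  st.nx = dims[0]; st.ny = dims[1]; st.nz = dims[2];
  st.ox = origin[0]; st.oy = origin[1]; st.oz = origin[2];
  st.sx = spacing[0]; st.sy = spacing[1]; st.sz = spacing[2];
  st.iso = iso;
  for (int k = 0; k + 1 < st.nz; ++k) {
    for (int j = 0; j + 1 < st.ny; ++j) {
      for (int i = 0; i + 1 < st.nx; ++i) {
        long c[8];
        c[0] = st.gid(i, j, k);       c[1] = st.gid(i + 1, j, k);
        c[2] = st.gid(i + 1, j + 1, k); c[3] = st.gid(i, j + 1, k);
        c[4] = st.gid(i, j, k + 1);   c[5] = st.gid(i + 1, j, k + 1);
        c[6] = st.gid(i + 1, j + 1, k + 1); c[7] = st.gid(i, j + 1, k + 1);
        // quick reject: all corners on one side
        bool any_in = false, any_out = false;
        for (int q = 0; q < 8; ++q) {
          if (st.v(c[q]) > iso) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;
        // six tets sharing diagonal c0-c6
        st.do_tet(c[0], c[1], c[2], c[6]);
        st.do_tet(c[0], c[2], c[3], c[6]);
        st.do_tet(c[0], c[3], c[7], c[6]);
        st.do_tet(c[0], c[7], c[4], c[6]);
        st.do_tet(c[0], c[4], c[5], c[6]);
        st.do_tet(c[0], c[5], c[1], c[6]);
      }
    }
  }
  int nv = (int)st.vx.size(), nf = (int)st.f0.size();
  NumericMatrix V(nv, 3);
  IntegerMatrix F(nf, 3);
  for (int q = 0; q < nv; ++q) { V(q, 0) = st.vx[q]; V(q, 1) = st.vy[q]; V(q, 2) = st.vz[q]; }
  for (int q = 0; q < nf; ++q) { F(q, 0) = st.f0[q]; F(q, 1) = st.f1[q]; F(q, 2) = st.f2[q]; }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Connected components over shared vertices; returns per-face component label.
// [[Rcpp::export]]
IntegerVector cpp_face_components(IntegerMatrix F, int nv) {
  int nf = F.nrow();
  std::vector<int> parent(nv);
  for (int i = 0; i < nv; ++i) parent[i] = i;
  struct UF {
    std::vector<int>& p;
    UF(std::vector<int>& p_) : p(p_) {}
    int find(int x) { while (p[x] != x) { p[x] = p[p[x]]; x = p[x]; } return x; }
    void unite(int a, int b) { a = find(a); b = find(b); if (a != b) p[a] = b; }
  } uf(parent);
  for (int t = 0; t < nf; ++t) {
    uf.unite(F(t, 0), F(t, 1));
    uf.unite(F(t, 0), F(t, 2));
  }
  IntegerVector lab(nf);
  for (int t = 0; t < nf; ++t) lab[t] = uf.find(F(t, 0));
  return lab;
}
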