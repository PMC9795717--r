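// Low-level volumetric kernels: separable Gaussian smoothing, cubic median
// filtering, exact squared Euclidean distance transform (Felzenszwalb &
// Huttenlocher), 26-connected component labelling, and iso-surface
// extraction by marching tetrahedra with shared-vertex deduplication.
//
// Volumes are passed as flat numeric/logical vectors with a dim attribute
// (nx, ny, nz), column-major as in R: index = i + nx*(j + ny*k), 0-based.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <queue>
#include <cstdint>
#include <cmath>
#include <algorithm>

using namespace Rcpp;

static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// ---------------------------------------------------------------------------
// Separable Gaussian smoothing (zero-padded boundary).
// ---------------------------------------------------------------------------

static void conv_axis(std::vector<double>& vol, int nx, int ny, int nz,
                      int axis, const std::vector<double>& kern) {
  const int r = (int)(kern.size() / 2);
  std::vector<double> out(vol.size());
  const int n[3] = {nx, ny, nz};
  const R_xlen_t stride[3] = {1, (R_xlen_t)nx, (R_xlen_t)nx * ny};
  const int len = n[axis];
  const R_xlen_t st = stride[axis];

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        const int pos[3] = {i, j, k};
        R_xlen_t base = idx3(i, j, k, nx, ny);
        double acc = 0.0;
        int p = pos[axis];
        int lo = std::max(0, p - r), hi = std::min(len - 1, p + r);
        for (int q = lo; q <= hi; ++q)
          acc += kern[(size_t)(q - p + r)] * vol[base + (R_xlen_t)(q - p) * st];
        out[base] = acc;
      }
    }
  }
  vol.swap(out);
}

// [[Rcpp::export]]
NumericVector smooth_gaussian_3d_cpp(NumericVector vol, IntegerVector dim,
                                     NumericVector sigma_vox) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  std::vector<double> v(vol.begin(), vol.end());
  for (int axis = 0; axis < 3; ++axis) {
    double s = sigma_vox[axis];
    if (s <= 0) continue;
    int r = std::max(1, (int)std::ceil(3.0 * s));
    std::vector<double> kern(2 * r + 1);
    double sum = 0.0;
    for (int q = -r; q <= r; ++q) {
      kern[q + r] = std::exp(-0.5 * q * q / (s * s));
      sum += kern[q + r];
    }
    for (double& w : kern) w /= sum;
    conv_axis(v, nx, ny, nz, axis, kern);
  }
  NumericVector out(v.begin(), v.end());
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 3D median filter, cubic neighbourhood (2r+1)^3, replicate boundary.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
NumericVector median_filter_3d_cpp(NumericVector vol, IntegerVector dim, int radius) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  if (radius <= 0) return clone(vol);
  NumericVector out(vol.size());
  std::vector<double> buf;
  buf.reserve((size_t)std::pow(2 * radius + 1, 3));
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        buf.clear();
        for (int dk = -radius; dk <= radius; ++dk) {
          int kk = std::min(nz - 1, std::max(0, k + dk));
          for (int dj = -radius; dj <= radius; ++dj) {
            int jj = std::min(ny - 1, std::max(0, j + dj));
            for (int di = -radius; di <= radius; ++di) {
              int ii = std::min(nx - 1, std::max(0, i + di));
              buf.push_back(vol[idx3(ii, jj, kk, nx, ny)]);
            }
          }
        }
        size_t mid = buf.size() / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        out[idx3(i, j, k, nx, ny)] = buf[mid];
      }
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform to the nearest FALSE voxel.
// Felzenszwalb & Huttenlocher lower-envelope algorithm, separable.
// Distances are in voxel units scaled by `spacing` per axis.
// ---------------------------------------------------------------------------

static const double DT_LARGE = 1e30;  // stands in for "no seed on this line"

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
                 double w, std::vector<int>& v, std::vector<double>& z) {
  // w = spacing along this axis; lower envelope of parabolas
  // (w*(x-q))^2 + f[q], Felzenszwalb & Huttenlocher
  const double INF = std::numeric_limits<double>::infinity();
  int kk = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  const double w2 = w * w;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + w2 * q * q) - (f[v[kk]] + w2 * v[kk] * v[kk])) /
               (2.0 * w2 * (q - v[kk]));
    while (s <= z[kk]) {
      --kk;
      s = ((f[q] + w2 * q * q) - (f[v[kk]] + w2 * v[kk] * v[kk])) /
          (2.0 * w2 * (q - v[kk]));
    }
    ++kk;
    v[kk] = q;
    z[kk] = s;
    z[kk + 1] = INF;
  }
  int m = 0;
  for (int q = 0; q < n; ++q) {
    while (z[m + 1] < (double)q) ++m;
    double dq = w * (q - v[m]);
    d[q] = std::min(DT_LARGE, dq * dq + f[v[m]]);
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector mask, IntegerVector dim, NumericVector spacing) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  std::vector<double> g(ntot);
  for (R_xlen_t t = 0; t < ntot; ++t) g[t] = mask[t] ? DT_LARGE : 0.0;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = idx3(0, j, k, nx, ny);
      for (int i = 0; i < nx; ++i) f[i] = g[base + i];
      dt1d(f, d, nx, spacing[0], v, z);
      for (int i = 0; i < nx; ++i) g[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      for (int j = 0; j < ny; ++j) f[j] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, ny, spacing[1], v, z);
      for (int j = 0; j < ny; ++j) g[idx3(i, j, k, nx, ny)] = d[j];
    }
  // pass along z
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      for (int k = 0; k < nz; ++k) f[k] = g[idx3(i, j, k, nx, ny)];
      dt1d(f, d, nz, spacing[2], v, z);
      for (int k = 0; k < nz; ++k) g[idx3(i, j, k, nx, ny)] = d[k];
    }

  NumericVector out(ntot);
  for (R_xlen_t t = 0; t < ntot; ++t)
    out[t] = (g[t] >= 0.5 * DT_LARGE) ? R_PosInf : g[t];
  out.attr("dim") = dim;
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected component labelling (BFS).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector label_components_cpp(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector labels(ntot, 0);
  int next_label = 0;
  std::vector<R_xlen_t> stack;

  for (R_xlen_t start = 0; start < ntot; ++start) {
    if (!mask[start] || labels[start] != 0) continue;
    ++next_label;
    stack.clear();
    stack.push_back(start);
    labels[start] = next_label;
    while (!stack.empty()) {
      R_xlen_t cur = stack.back();
      stack.pop_back();
      int i = (int)(cur % nx);
      int j = (int)((cur / nx) % ny);
      int k = (int)(cur / ((R_xlen_t)nx * ny));
      for (int dk = -1; dk <= 1; ++dk)
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            if (!di && !dj && !dk) continue;
            int ii = i + di, jj = j + dj, kk = k + dk;
            if (ii < 0 || jj < 0 || kk < 0 || ii >= nx || jj >= ny || kk >= nz)
              continue;
            R_xlen_t nb = idx3(ii, jj, kk, nx, ny);
            if (mask[nb] && labels[nb] == 0) {
              labels[nb] = next_label;
              stack.push_back(nb);
            }
          }
    }
  }
  labels.attr("dim") = dim;
  return labels;
}

// ---------------------------------------------------------------------------
// Marching tetrahedra. The scalar field is sampled at voxel centres; node
// (i,j,k) sits at origin + (i + 0.5) * spacing. Each lattice cube is split
// into six tetrahedra sharing the main diagonal; crossing vertices are
// linearly interpolated and deduplicated on lattice edges, so meshes from
// fields that change sign only in the interior are watertight. Triangles are
// wound counter-clockwise as seen from outside (normals away from the
// super-level set, i.e. away from the foreground).
// ---------------------------------------------------------------------------

struct MTAccum {
  std::unordered_map<uint64_t, int> edge_vertex;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;
};

static int edge_point(MTAccum& acc, uint64_t ida, uint64_t idb,
                      const double* pa, const double* pb,
                      double va, double vb, double level) {
  uint64_t key = (std::min(ida, idb) << 32) | std::max(ida, idb);
  auto it = acc.edge_vertex.find(key);
  if (it != acc.edge_vertex.end()) return it->second;
  double t = (level - va) / (vb - va);
  int id = (int)acc.vx.size();
  acc.vx.push_back(pa[0] + t * (pb[0] - pa[0]));
  acc.vy.push_back(pa[1] + t * (pb[1] - pa[1]));
  acc.vz.push_back(pa[2] + t * (pb[2] - pa[2]));
  acc.edge_vertex.emplace(key, id);
  return id;
}

static void emit_triangle(MTAccum& acc, int a, int b, int c,
                          const double in_centroid[3]) {
  // orient so the normal points away from the interior of the foreground
  double ax = acc.vx[a], ay = acc.vy[a], az = acc.vz[a];
  double ux = acc.vx[b] - ax, uy = acc.vy[b] - ay, uz = acc.vz[b] - az;
  double wx = acc.vx[c] - ax, wy = acc.vy[c] - ay, wz = acc.vz[c] - az;
  double nxv = uy * wz - uz * wy;
  double nyv = uz * wx - ux * wz;
  double nzv = ux * wy - uy * wx;
  double cx = (ax + acc.vx[b] + acc.vx[c]) / 3.0;
  double cy = (ay + acc.vy[b] + acc.vy[c]) / 3.0;
  double cz = (az + acc.vz[b] + acc.vz[c]) / 3.0;
  double rx = in_centroid[0] - cx, ry = in_centroid[1] - cy, rz = in_centroid[2] - cz;
  if (nxv * rx + nyv * ry + nzv * rz > 0) std::swap(b, c);
  acc.f0.push_back(a);
  acc.f1.push_back(b);
  acc.f2.push_back(c);
}

// [[Rcpp::export]]
List marching_tetrahedra_cpp(NumericVector field, IntegerVector dim, double level,
                             NumericVector spacing, NumericVector origin) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  double dx = spacing[0], dy = spacing[1], dz = spacing[2];
  double ox = origin[0], oy = origin[1], oz = origin[2];

  // six tetrahedra around the 0-7 diagonal of the unit cube
  static const int tets[6][4] = {
    {0, 1, 3, 7}, {0, 3, 2, 7}, {0, 2, 6, 7},
    {0, 6, 4, 7}, {0, 4, 5, 7}, {0, 5, 1, 7}};
  static const int corner_off[8][3] = {
    {0, 0, 0}, {1, 0, 0}, {0, 1, 0}, {1, 1, 0},
    {0, 0, 1}, {1, 0, 1}, {0, 1, 1}, {1, 1, 1}};

  MTAccum acc;

  for (int k = 0; k + 1 < nz; ++k)
    for (int j = 0; j + 1 < ny; ++j)
      for (int i = 0; i + 1 < nx; ++i) {
        double val[8];
        uint64_t gid[8];
        double pos[8][3];
        bool any_in = false, any_out = false;
        for (int c = 0; c < 8; ++c) {
          int ci = i + corner_off[c][0];
          int cj = j + corner_off[c][1];
          int ck = k + corner_off[c][2];
          val[c] = field[idx3(ci, cj, ck, nx, ny)];
          gid[c] = (uint64_t)idx3(ci, cj, ck, nx, ny);
          pos[c][0] = ox + (ci + 0.5) * dx;
          pos[c][1] = oy + (cj + 0.5) * dy;
          pos[c][2] = oz + (ck + 0.5) * dz;
          if (val[c] > level) any_in = true; else any_out = true;
        }
        if (!any_in || !any_out) continue;

        for (int t = 0; t < 6; ++t) {
          const int* tv = tets[t];
          int inside[4], n_in = 0;
          for (int c = 0; c < 4; ++c)
            if (val[tv[c]] > level) inside[n_in++] = c;
          if (n_in == 0 || n_in == 4) continue;

          double cen[3] = {0, 0, 0};
          for (int c = 0; c < n_in; ++c)
            for (int a = 0; a < 3; ++a) cen[a] += pos[tv[inside[c]]][a];
          for (int a = 0; a < 3; ++a) cen[a] /= n_in;

          auto ep = [&](int ca, int cb) {
            return edge_point(acc, gid[tv[ca]], gid[tv[cb]], pos[tv[ca]],
                              pos[tv[cb]], val[tv[ca]], val[tv[cb]], level);
          };

          if (n_in == 1) {
            int a = inside[0];
            int o[3], m = 0;
            for (int c = 0; c < 4; ++c) if (c != a) o[m++] = c;
            emit_triangle(acc, ep(a, o[0]), ep(a, o[1]), ep(a, o[2]), cen);
          } else if (n_in == 3) {
            int a = -1;  // the single outside vertex
            bool used[4] = {false, false, false, false};
            for (int c = 0; c < n_in; ++c) used[inside[c]] = true;
            for (int c = 0; c < 4; ++c) if (!used[c]) a = c;
            int o[3], m = 0;
            for (int c = 0; c < 4; ++c) if (c != a) o[m++] = c;
            emit_triangle(acc, ep(o[0], a), ep(o[1], a), ep(o[2], a), cen);
          } else {  // n_in == 2: quad on four crossing edges
            int a = inside[0], b = inside[1];
            int o[2], m = 0;
            for (int c = 0; c < 4; ++c)
              if (c != a && c != b) o[m++] = c;
            int p1 = ep(a, o[0]), p2 = ep(a, o[1]);
            int p3 = ep(b, o[0]), p4 = ep(b, o[1]);
            emit_triangle(acc, p1, p2, p3, cen);
            emit_triangle(acc, p3, p2, p4, cen);
          }
        }
      }

  int nvert = (int)acc.vx.size();
  NumericMatrix V(nvert, 3);
  for (int t = 0; t < nvert; ++t) {
    V(t, 0) = acc.vx[t];
    V(t, 1) = acc.vy[t];
    V(t, 2) = acc.vz[t];
  }
  int nface = (int)acc.f0.size();
  IntegerMatrix F(nface, 3);
  for (int t = 0; t < nface; ++t) {
    F(t, 0) = acc.f0[t] + 1;
    F(t, 1) = acc.f1[t] + 1;
    F(t, 2) = acc.f2[t] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}
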