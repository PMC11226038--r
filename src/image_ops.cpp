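// Low-level 3D image primitives shared by the segmentation stage.
//
// Conventions (fixed across the package):
//  - voxel grids are dense arrays of size nx*ny*nz, linear index
//    i = x + nx*(y + ny*z), 0-based. Increasing linear index therefore
//    enumerates voxels in lexicographic (z, y, x) order with z most
//    significant, which is the documented deterministic scan order.
//  - all neighbourhood operations use 26-connectivity.
//  - out-of-grid access is handled by replicate (nearest-value) padding
//    for filters, and simply skipped for connectivity operations.

#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <queue>
#include <vector>

using namespace Rcpp;

namespace {

inline int clampi(int v, int lo, int hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

inline R_xlen_t lin(int x, int y, int z, int nx, int ny) {
  return (R_xlen_t)x + (R_xlen_t)nx * ((R_xlen_t)y + (R_xlen_t)ny * (R_xlen_t)z);
}

}  // namespace

// [[Rcpp::export(name = ".cpp_median_filter3")]]
NumericVector cpp_median_filter3(NumericVector values, IntegerVector dm,
                                 int radius) {
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  if (radius <= 0) return clone(values);
  NumericVector out(values.size());
  const int w = 2 * radius + 1;
  std::vector<double> buf((size_t)w * w * w);
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        int k = 0;
        for (int dz = -radius; dz <= radius; ++dz) {
          const int zz = clampi(z + dz, 0, nz - 1);
          for (int dy = -radius; dy <= radius; ++dy) {
            const int yy = clampi(y + dy, 0, ny - 1);
            for (int dx = -radius; dx <= radius; ++dx) {
              const int xx = clampi(x + dx, 0, nx - 1);
              buf[k++] = values[lin(xx, yy, zz, nx, ny)];
            }
          }
        }
        std::nth_element(buf.begin(), buf.begin() + k / 2, buf.begin() + k);
        out[lin(x, y, z, nx, ny)] = buf[k / 2];
      }
    }
  }
  return out;
}

// Separable Gaussian, kernel truncated at 4 sigma, replicate padding.
// [[Rcpp::export(name = ".cpp_gaussian_blur3")]]
NumericVector cpp_gaussian_blur3(NumericVector values, IntegerVector dm,
                                 double sigma_vox) {
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  if (sigma_vox <= 0) return clone(values);
  const int r = (int)std::ceil(4.0 * sigma_vox);
  std::vector<double> k(2 * r + 1);
  double s = 0.0;
  for (int i = -r; i <= r; ++i) {
    k[i + r] = std::exp(-(double)i * i / (2.0 * sigma_vox * sigma_vox));
    s += k[i + r];
  }
  for (double& v : k) v /= s;

  std::vector<double> a(values.begin(), values.end());
  std::vector<double> b(a.size());
  const int n[3] = {nx, ny, nz};
  for (int axis = 0; axis < 3; ++axis) {
    for (int z = 0; z < nz; ++z) {
      for (int y = 0; y < ny; ++y) {
        for (int x = 0; x < nx; ++x) {
          double acc = 0.0;
          const int c[3] = {x, y, z};
          for (int i = -r; i <= r; ++i) {
            int q[3] = {x, y, z};
            q[axis] = clampi(c[axis] + i, 0, n[axis] - 1);
            acc += k[i + r] * a[lin(q[0], q[1], q[2], nx, ny)];
          }
          b[lin(x, y, z, nx, ny)] = acc;
        }
      }
    }
    std::swap(a, b);
  }
  return NumericVector(a.begin(), a.end());
}

// Gradient magnitude by central differences (one-sided at the faces),
// in intensity units per voxel.
// [[Rcpp::export(name = ".cpp_gradient_magnitude3")]]
NumericVector cpp_gradient_magnitude3(NumericVector values, IntegerVector dm) {
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  NumericVector out(values.size());
  for (int z = 0; z < nz; ++z) {
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) {
        const int x0 = clampi(x - 1, 0, nx - 1), x1 = clampi(x + 1, 0, nx - 1);
        const int y0 = clampi(y - 1, 0, ny - 1), y1 = clampi(y + 1, 0, ny - 1);
        const int z0 = clampi(z - 1, 0, nz - 1), z1 = clampi(z + 1, 0, nz - 1);
        const double gx = (values[lin(x1, y, z, nx, ny)] -
                           values[lin(x0, y, z, nx, ny)]) / (double)(x1 - x0);
        const double gy = (values[lin(x, y1, z, nx, ny)] -
                           values[lin(x, y0, z, nx, ny)]) / (double)(y1 - y0);
        const double gz = (values[lin(x, y, z1, nx, ny)] -
                           values[lin(x, y, z0, nx, ny)]) / (double)(z1 - z0);
        out[lin(x, y, z, nx, ny)] = std::sqrt(gx * gx + gy * gy + gz * gz);
      }
    }
  }
  return out;
}

namespace {

// Felzenszwalb & Huttenlocher 1D squared distance transform.
void dt1d(const std::vector<double>& f, std::vector<double>& d, int n,
          std::vector<int>& v, std::vector<double>& zb) {
  int k = 0;
  v[0] = 0;
  zb[0] = -HUGE_VAL;
  zb[1] = HUGE_VAL;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= zb[k]) {
        --k;
      } else {
        break;
      }
    }
    ++k;
    v[k] = q;
    zb[k] = s;
    zb[k + 1] = HUGE_VAL;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (zb[k + 1] < q) ++k;
    const double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

}  // namespace

// Exact squared Euclidean distance (in voxel units) from each voxel to the
// nearest background (mask == FALSE) voxel; 0 outside the mask.
// [[Rcpp::export(name = ".cpp_edt_sq3")]]
NumericVector cpp_edt_sq3(LogicalVector mask, IntegerVector dm) {
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  // finite surrogate for +infinity keeps the parabola-intersection
  // arithmetic NaN-free; any reachable squared distance is < 3 * 200^2
  const double kFar = 1e10;
  std::vector<double> g(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) g[i] = mask[i] ? kFar : 0.0;

  const int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax);
  std::vector<int> v(nmax);
  std::vector<double> zb(nmax + 1);

  // x pass
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = g[lin(x, y, z, nx, ny)];
      dt1d(f, d, nx, v, zb);
      for (int x = 0; x < nx; ++x) g[lin(x, y, z, nx, ny)] = d[x];
    }
  // y pass
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = g[lin(x, y, z, nx, ny)];
      dt1d(f, d, ny, v, zb);
      for (int y = 0; y < ny; ++y) g[lin(x, y, z, nx, ny)] = d[y];
    }
  // z pass
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = g[lin(x, y, z, nx, ny)];
      dt1d(f, d, nz, v, zb);
      for (int z = 0; z < nz; ++z) g[lin(x, y, z, nx, ny)] = d[z];
    }
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i) out[i] = g[i];
  return out;
}

// 26-connected components of a logical mask. Components are numbered 1..k in
// order of their first voxel in scan order, which makes labelling a pure
// function of the mask.
// [[Rcpp::export(name = ".cpp_label_components3")]]
IntegerVector cpp_label_components3(LogicalVector mask, IntegerVector dm) {
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (R_xlen_t i = 0; i < ntot; ++i) {
    if (!mask[i] || lab[i] != 0) continue;
    ++next;
    lab[i] = next;
    stack.push_back(i);
    while (!stack.empty()) {
      const R_xlen_t cur = stack.back();
      stack.pop_back();
      const int cz = (int)(cur / ((R_xlen_t)nx * ny));
      const int cy = (int)((cur / nx) % ny);
      const int cx = (int)(cur % nx);
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (dx == 0 && dy == 0 && dz == 0) continue;
            const int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
              continue;
            const R_xlen_t j = lin(xx, yy, zz, nx, ny);
            if (mask[j] && lab[j] == 0) {
              lab[j] = next;
              stack.push_back(j);
            }
          }
    }
  }
  return lab;
}

namespace {

struct WsNode {
  double p;
  R_xlen_t seq;
  int lab;
  R_xlen_t idx;
};

// min-heap ordering: lowest priority first; among equal priorities,
// insertion (FIFO) order. FIFO plateau handling grows equal-priority
// regions in balanced breadth-first layers from all competing markers
// (standard watershed semantics); the insertion sequence itself is
// deterministic because seeds enter in (label, scan-order) order and
// neighbours are pushed in fixed lexicographic offset order.
struct WsCmp {
  bool operator()(const WsNode& a, const WsNode& b) const {
    if (a.p != b.p) return a.p > b.p;
    return a.seq > b.seq;
  }
};

}  // namespace

// Marker-based priority-flood watershed restricted to a mask. Seed voxels
// pre-claim their own labels (a marker can never be overrun by a competing
// flood); every other mask voxel takes the label of the first queue entry
// that reaches it in WsCmp order.
// [[Rcpp::export(name = ".cpp_watershed_flood3")]]
IntegerVector cpp_watershed_flood3(NumericVector priority, LogicalVector mask,
                                   IntegerVector seeds, IntegerVector dm) {
  const int nx = dm[0], ny = dm[1], nz = dm[2];
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(ntot, 0);
  std::vector<char> done(ntot, 0);
  std::priority_queue<WsNode, std::vector<WsNode>, WsCmp> pq;
  std::vector<std::pair<int, R_xlen_t> > sv;
  for (R_xlen_t i = 0; i < ntot; ++i) {
    if (seeds[i] > 0 && mask[i]) sv.push_back(std::make_pair(seeds[i], i));
  }
  std::sort(sv.begin(), sv.end());
  R_xlen_t seq = 0;
  for (size_t s = 0; s < sv.size(); ++s) {
    lab[sv[s].second] = sv[s].first;
    pq.push(WsNode{priority[sv[s].second], seq++, sv[s].first,
                   sv[s].second});
  }
  while (!pq.empty()) {
    const WsNode n = pq.top();
    pq.pop();
    if (done[n.idx]) continue;
    done[n.idx] = 1;
    if (lab[n.idx] == 0) lab[n.idx] = n.lab;
    const int mylab = lab[n.idx];
    const int cz = (int)(n.idx / ((R_xlen_t)nx * ny));
    const int cy = (int)((n.idx / nx) % ny);
    const int cx = (int)(n.idx % nx);
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (dx == 0 && dy == 0 && dz == 0) continue;
          const int xx = cx + dx, yy = cy + dy, zz = cz + dz;
          if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz)
            continue;
          const R_xlen_t j = lin(xx, yy, zz, nx, ny);
          if (mask[j] && !done[j] && lab[j] == 0) {
            pq.push(WsNode{priority[j], seq++, mylab, j});
          }
        }
  }
  return lab;
}
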