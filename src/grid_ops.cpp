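#include <Rcpp.h>
#include <queue>
#include <cmath>
#include <limits>
using namespace Rcpp;

// ---- 1D squared distance transform (Felzenszwalb & Huttenlocher 2012) ----
// f: input squared distances along a scan line, d: output, n: length.
// v, z: scratch (size n, n+1).
static void dt1d(const double *f, double *d, int n, int *v, double *z) {
  const double INF = std::numeric_limits<double>::infinity();
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + (double)q * q) - (f[v[k]] + (double)v[k] * v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared Euclidean distance (in voxel units) from every voxel to the
// nearest feature voxel. dims = c(nx, ny, nz), column-major (R array order).
// [[Rcpp::export(name = ".edt3d_sq")]]
NumericVector edt3d_sq(LogicalVector feature, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  // large finite stand-in for "no feature": infinities would propagate
  // NaN through the parabola intersection formula
  const double BIG = 1e15;
  const R_xlen_t ntot = (R_xlen_t)nx * ny * nz;
  NumericVector out(ntot);
  for (R_xlen_t i = 0; i < ntot; ++i)
    out[i] = feature[i] ? 0.0 : BIG;

  int nmax = std::max(nx, std::max(ny, nz));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along x
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + (R_xlen_t)j * nx;
      for (int i = 0; i < nx; ++i) f[i] = out[base + i];
      dt1d(f.data(), d.data(), nx, v.data(), z.data());
      for (int i = 0; i < nx; ++i) out[base + i] = d[i];
    }
  // pass along y
  for (int k = 0; k < nz; ++k)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)k * nx * ny + i;
      for (int j = 0; j < ny; ++j) f[j] = out[base + (R_xlen_t)j * nx];
      dt1d(f.data(), d.data(), ny, v.data(), z.data());
      for (int j = 0; j < ny; ++j) out[base + (R_xlen_t)j * nx] = d[j];
    }
  // pass along z
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      R_xlen_t base = (R_xlen_t)j * nx + i;
      for (int k = 0; k < nz; ++k) f[k] = out[base + (R_xlen_t)k * nxy];
      dt1d(f.data(), d.data(), nz, v.data(), z.data());
      for (int k = 0; k < nz; ++k) out[base + (R_xlen_t)k * nxy] = d[k];
    }
  return out;
}

// 6-connected flood fill over open (non-blocked) voxels, seeded from all
// open voxels on the grid boundary. Returns reachability mask.
// [[Rcpp::export(name = ".floodfill6")]]
LogicalVector floodfill6(LogicalVector blocked, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const R_xlen_t ntot = nxy * nz;
  LogicalVector reach(ntot, false);
  std::queue<R_xlen_t> q;

  auto push = [&](int i, int j, int k) {
    R_xlen_t idx = (R_xlen_t)k * nxy + (R_xlen_t)j * nx + i;
    if (!blocked[idx] && !reach[idx]) {
      reach[idx] = true;
      q.push(idx);
    }
  };
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i)
        if (i == 0 || j == 0 || k == 0 || i == nx - 1 || j == ny - 1 ||
            k == nz - 1)
          push(i, j, k);

  while (!q.empty()) {
    R_xlen_t idx = q.front();
    q.pop();
    int k = (int)(idx / nxy);
    int rem = (int)(idx % nxy);
    int j = rem / nx;
    int i = rem % nx;
    if (i > 0) push(i - 1, j, k);
    if (i < nx - 1) push(i + 1, j, k);
    if (j > 0) push(i, j - 1, k);
    if (j < ny - 1) push(i, j + 1, k);
    if (k > 0) push(i, j, k - 1);
    if (k < nz - 1) push(i, j, k + 1);
  }
  return reach;
}

// First-hit ray casting by voxel traversal (Amanatides & Woo DDA).
// labels: flattened label grid (column-major), dims its dimensions;
// surface voxels carry label == surface_label. centers are given in
// continuous voxel coordinates (voxel [i,j,k] center at (i,j,k), 0-based).
// For each (center, dir) returns the 1-based linear index of the first
// surface voxel the ray passes through, or 0 if it leaves the grid.
// [[Rcpp::export(name = ".raycast_hits")]]
IntegerMatrix raycast_hits(IntegerVector labels, IntegerVector dims,
                           NumericMatrix centers, NumericMatrix dirs,
                           int surface_label) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const int m = centers.nrow(), r = dirs.nrow();
  const double INF = std::numeric_limits<double>::infinity();
  IntegerMatrix hits(m, r);
  for (int c = 0; c < m; ++c) {
    const double u0[3] = {centers(c, 0), centers(c, 1), centers(c, 2)};
    for (int d = 0; d < r; ++d) {
      const double dir[3] = {dirs(d, 0), dirs(d, 1), dirs(d, 2)};
      int iv[3], step[3];
      double tmax[3], tdelta[3];
      bool inside = true;
      for (int a = 0; a < 3; ++a) {
        iv[a] = (int)std::floor(u0[a] + 0.5);
        int na = (a == 0) ? nx : (a == 1 ? ny : nz);
        if (iv[a] < 0 || iv[a] >= na) inside = false;
        if (dir[a] > 0) {
          step[a] = 1;
          tmax[a] = ((iv[a] + 0.5) - u0[a]) / dir[a];
          tdelta[a] = 1.0 / dir[a];
        } else if (dir[a] < 0) {
          step[a] = -1;
          tmax[a] = ((iv[a] - 0.5) - u0[a]) / dir[a];
          tdelta[a] = -1.0 / dir[a];
        } else {
          step[a] = 0;
          tmax[a] = INF;
          tdelta[a] = INF;
        }
      }
      int hit = 0;
      while (inside) {
        R_xlen_t lin = (R_xlen_t)iv[2] * nxy + (R_xlen_t)iv[1] * nx + iv[0];
        if (labels[lin] == surface_label) {
          hit = (int)(lin + 1);
          break;
        }
        int a = 0;
        if (tmax[1] < tmax[a]) a = 1;
        if (tmax[2] < tmax[a]) a = 2;
        iv[a] += step[a];
        tmax[a] += tdelta[a];
        int na = (a == 0) ? nx : (a == 1 ? ny : nz);
        if (iv[a] < 0 || iv[a] >= na) inside = false;
      }
      hits(c, d) = hit;
    }
  }
  return hits;
}
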