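#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

// Voxel arrays are R arrays in column-major order with dims = (nx, ny, nz);
// linear index i = x + nx*(y + ny*z) for zero-based x, y, z.

static inline int lin(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---------------------------------------------------------------------------
// Connected component labeling (6 / 18 / 26 connectivity), BFS flood fill.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector cc_label_cpp(LogicalVector grid, IntegerVector dims, int connectivity) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  if (grid.size() != n) stop("grid/dims mismatch");

  // neighbor offsets for the requested connectivity
  std::vector<int> ox, oy, oz;
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        if (dx == 0 && dy == 0 && dz == 0) continue;
        int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
        if ((connectivity == 6 && s > 1) || (connectivity == 18 && s > 2)) continue;
        ox.push_back(dx); oy.push_back(dy); oz.push_back(dz);
      }
  const int noff = (int)ox.size();

  IntegerVector labels(n, 0);
  std::vector<int> stack;
  int cur = 0;
  for (int i = 0; i < n; ++i) {
    if (!grid[i] || labels[i] != 0) continue;
    ++cur;
    labels[i] = cur;
    stack.clear();
    stack.push_back(i);
    while (!stack.empty()) {
      int v = stack.back(); stack.pop_back();
      int x = v % nx, y = (v / nx) % ny, z = v / (nx * ny);
      for (int k = 0; k < noff; ++k) {
        int xx = x + ox[k], yy = y + oy[k], zz = z + oz[k];
        if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
        int u = lin(xx, yy, zz, nx, ny);
        if (grid[u] && labels[u] == 0) { labels[u] = cur; stack.push_back(u); }
      }
    }
  }
  return labels;
}

// ---------------------------------------------------------------------------
// 26-neighbor foreground counts for every voxel.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerVector count_nbrs26_cpp(LogicalVector grid, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  IntegerVector out(n, 0);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = lin(x, y, z, nx, ny);
        if (!grid[i]) continue;
        int c = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= nx || yy >= ny || zz >= nz) continue;
              if (grid[lin(xx, yy, zz, nx, ny)]) ++c;
            }
        out[i] = c;
      }
  return out;
}

// ---------------------------------------------------------------------------
// Anisotropic squared Euclidean distance transform (Felzenszwalb-Huttenlocher
// lower-envelope algorithm applied separably along each axis). Returns, for
// every foreground voxel, the squared physical distance to the nearest
// background voxel center; 0 on background.
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n, double w) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> zb(n + 1);
  int k = 0;
  v[0] = 0; zb[0] = -INF; zb[1] = INF;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      double xq = q * w, xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2.0 * xq - 2.0 * xv);
      if (k > 0 && s <= zb[k]) { --k; } else break;
    }
    ++k; v[k] = q; zb[k] = s; zb[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    double x = q * w;
    while (zb[k + 1] < x) ++k;
    double dx = x - v[k] * w;
    d[q] = dx * dx + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector edt_sq_cpp(LogicalVector grid, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  const double BIG = 1e30;
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = grid[i] ? BIG : 0.0;

  std::vector<double> f, d;

  // along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y) {
      for (int x = 0; x < nx; ++x) f[x] = out[lin(x, y, z, nx, ny)];
      dt1d(f, d, nx, spacing[0]);
      for (int x = 0; x < nx; ++x) out[lin(x, y, z, nx, ny)] = d[x];
    }
  // along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; ++z)
    for (int x = 0; x < nx; ++x) {
      for (int y = 0; y < ny; ++y) f[y] = out[lin(x, y, z, nx, ny)];
      dt1d(f, d, ny, spacing[1]);
      for (int y = 0; y < ny; ++y) out[lin(x, y, z, nx, ny)] = d[y];
    }
  // along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; ++y)
    for (int x = 0; x < nx; ++x) {
      for (int z = 0; z < nz; ++z) f[z] = out[lin(x, y, z, nx, ny)];
      dt1d(f, d, nz, spacing[2]);
      for (int z = 0; z < nz; ++z) out[lin(x, y, z, nx, ny)] = d[z];
    }
  for (int i = 0; i < n; ++i) if (out[i] >= BIG) out[i] = R_PosInf;
  return out;
}

// ---------------------------------------------------------------------------
// Topology-preserving 3D thinning for (26, 6) digital topology.
//
// Border voxels are peeled in six directional subiterations; a voxel is
// deleted only if it is a simple point (Bertrand-Malandain characterization:
// exactly one 26-component of foreground in the punctured 3x3x3 neighborhood
// AND exactly one 6-component of background within the 18-neighborhood that
// touches a face neighbor) and not a curve endpoint (exactly one foreground
// 26-neighbor). Deletions are sequential, so topology is preserved exactly.
// ---------------------------------------------------------------------------

// 3x3x3 neighborhood layout: idx = (dz+1)*9 + (dy+1)*3 + (dx+1); center = 13.

static bool is_simple(const bool nb[27]) {
  // condition A: one 26-component of foreground among the 26 neighbors
  int lblA[27]; for (int i = 0; i < 27; ++i) lblA[i] = 0;
  int ncompA = 0;
  int stack[27];
  for (int i = 0; i < 27; ++i) {
    if (i == 13 || !nb[i] || lblA[i]) continue;
    ++ncompA;
    if (ncompA > 1) return false;
    int top = 0; stack[top++] = i; lblA[i] = ncompA;
    while (top > 0) {
      int v = stack[--top];
      int vx = v % 3, vy = (v / 3) % 3, vz = v / 9;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            int xx = vx + dx, yy = vy + dy, zz = vz + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
            int u = zz * 9 + yy * 3 + xx;
            if (u == 13 || u == v) continue;
            if (nb[u] && !lblA[u]) { lblA[u] = ncompA; stack[top++] = u; }
          }
    }
  }
  if (ncompA != 1) return false;

  // condition B: 6-components of background restricted to the 18-neighborhood,
  // counting only those containing a face neighbor of the center.
  // cell is in 18-neighborhood if |dx|+|dy|+|dz| is 1 or 2.
  bool in18[27]; bool bg18[27];
  for (int i = 0; i < 27; ++i) {
    int dx = (i % 3) - 1, dy = ((i / 3) % 3) - 1, dz = (i / 9) - 1;
    int s = std::abs(dx) + std::abs(dy) + std::abs(dz);
    in18[i] = (s == 1 || s == 2);
    bg18[i] = in18[i] && !nb[i];
  }
  int lblB[27]; for (int i = 0; i < 27; ++i) lblB[i] = 0;
  int ncompB = 0;
  for (int i = 0; i < 27; ++i) {
    if (!bg18[i] || lblB[i]) continue;
    int dx0 = (i % 3) - 1, dy0 = ((i / 3) % 3) - 1, dz0 = (i / 9) - 1;
    // only seed from face neighbors; other bg cells may join via flood fill
    if (std::abs(dx0) + std::abs(dy0) + std::abs(dz0) != 1) continue;
    ++ncompB;
    if (ncompB > 1) return false;
    int top = 0; stack[top++] = i; lblB[i] = ncompB;
    while (top > 0) {
      int v = stack[--top];
      int vx = v % 3, vy = (v / 3) % 3, vz = v / 9;
      const int face[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int k = 0; k < 6; ++k) {
        int xx = vx + face[k][0], yy = vy + face[k][1], zz = vz + face[k][2];
        if (xx < 0 || yy < 0 || zz < 0 || xx > 2 || yy > 2 || zz > 2) continue;
        int u = zz * 9 + yy * 3 + xx;
        if (bg18[u] && !lblB[u]) { lblB[u] = ncompB; stack[top++] = u; }
      }
    }
  }
  return ncompB == 1;
}

static inline void fill_neighborhood(const std::vector<char>& g, int x, int y, int z,
                                     int nx, int ny, int nz, bool nb[27]) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool v = false;
        if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
          v = g[lin(xx, yy, zz, nx, ny)] != 0;
        nb[(dz + 1) * 9 + (dy + 1) * 3 + (dx + 1)] = v;
      }
}

// [[Rcpp::export]]
LogicalVector thin_cpp(LogicalVector grid, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  std::vector<char> g(n);
  for (int i = 0; i < n; ++i) g[i] = grid[i] ? 1 : 0;

  const int dirs[6][3] = {{0,0,-1},{0,0,1},{0,-1,0},{0,1,0},{-1,0,0},{1,0,0}};
  bool nb[27];
  std::vector<int> cand;
  bool changed = true;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; ++d) {
      cand.clear();
      for (int z = 0; z < nz; ++z)
        for (int y = 0; y < ny; ++y)
          for (int x = 0; x < nx; ++x) {
            int i = lin(x, y, z, nx, ny);
            if (!g[i]) continue;
            int xx = x + dirs[d][0], yy = y + dirs[d][1], zz = z + dirs[d][2];
            bool bgnbr = true;
            if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
              bgnbr = !g[lin(xx, yy, zz, nx, ny)];
            if (bgnbr) cand.push_back(i);
          }
      for (size_t c = 0; c < cand.size(); ++c) {
        int i = cand[c];
        if (!g[i]) continue;
        int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
        // border condition may have changed; re-check
        int xx = x + dirs[d][0], yy = y + dirs[d][1], zz = z + dirs[d][2];
        bool bgnbr = true;
        if (xx >= 0 && yy >= 0 && zz >= 0 && xx < nx && yy < ny && zz < nz)
          bgnbr = !g[lin(xx, yy, zz, nx, ny)];
        if (!bgnbr) continue;
        fill_neighborhood(g, x, y, z, nx, ny, nz, nb);
        int cnt = 0;
        for (int k = 0; k < 27; ++k) if (k != 13 && nb[k]) ++cnt;
        if (cnt <= 1) continue;   // endpoint or isolated voxel: preserve
        if (is_simple(nb)) { g[i] = 0; changed = true; }
      }
    }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = g[i] != 0;
  out.attr("dim") = dims;
  return out;
}
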