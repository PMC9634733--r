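// 3-D image utilities: anisotropic Euclidean distance transform,
// topology-preserving thinning (curve skeleton), connected components,
// tube rasterization for the phantom, nearest-centerline labeling and
// rigid patch rotation. Voxel indices are 0-based, column-major
// (idx = x + nx*(y + ny*z)) to match R array layout.

#include <RcppArmadillo.h>
#include <queue>
#include <vector>
#include <cmath>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// ---------------------------------------------------------------------------
// Euclidean distance transform (Felzenszwalb & Huttenlocher, separable),
// with per-axis voxel spacing. Input: f = 0 on background, INF on
// foreground gives distance-to-background; we expose distance of each
// foreground voxel to the nearest background voxel (outside = 0).

static void dt1d(const std::vector<double>& f, std::vector<double>& d,
                 int n, double w2) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -INFINITY;
  z[1] = INFINITY;
  for (int q = 1; q < n; q++) {
    double s;
    while (true) {
      s = ((f[q] + w2 * q * q) - (f[v[k]] + w2 * v[k] * v[k])) /
          (2.0 * w2 * q - 2.0 * w2 * v[k]);
      if (s <= z[k]) { k--; } else break;
    }
    k++;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INFINITY;
  }
  k = 0;
  for (int q = 0; q < n; q++) {
    while (z[k + 1] < q) k++;
    double dq = (double)q - v[k];
    d[q] = w2 * dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt(LogicalVector mask, IntegerVector dims,
                      NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double BIG = 1e30;
  std::vector<double> g((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); i++) g[i] = mask[i] ? BIG : 0.0;

  std::vector<double> f, d;
  // pass along x
  f.resize(nx); d.resize(nx);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++) {
      size_t base = (size_t)nx * (y + (size_t)ny * z);
      for (int x = 0; x < nx; x++) f[x] = g[base + x];
      dt1d(f, d, nx, spacing[0] * spacing[0]);
      for (int x = 0; x < nx; x++) g[base + x] = d[x];
    }
  // pass along y
  f.resize(ny); d.resize(ny);
  for (int z = 0; z < nz; z++)
    for (int x = 0; x < nx; x++) {
      for (int y = 0; y < ny; y++) f[y] = g[x + (size_t)nx * (y + (size_t)ny * z)];
      dt1d(f, d, ny, spacing[1] * spacing[1]);
      for (int y = 0; y < ny; y++) g[x + (size_t)nx * (y + (size_t)ny * z)] = d[y];
    }
  // pass along z
  f.resize(nz); d.resize(nz);
  for (int y = 0; y < ny; y++)
    for (int x = 0; x < nx; x++) {
      for (int z = 0; z < nz; z++) f[z] = g[x + (size_t)nx * (y + (size_t)ny * z)];
      dt1d(f, d, nz, spacing[2] * spacing[2]);
      for (int z = 0; z < nz; z++) g[x + (size_t)nx * (y + (size_t)ny * z)] = d[z];
    }

  NumericVector out((size_t)nx * ny * nz);
  for (size_t i = 0; i < g.size(); i++) out[i] = std::sqrt(g[i]);
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Simple-point test (26-connectivity foreground / 6-connectivity background).
// nb: 27 occupancy values of the 3x3x3 neighborhood, index
// (dx+1) + 3*(dy+1) + 9*(dz+1); center at 13.

static inline int off2idx(int dx, int dy, int dz) {
  return (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
}

static bool is_simple(const bool nb[27]) {
  // condition A: exactly one 26-component of foreground among the 26 nbrs
  bool fg[27];
  for (int i = 0; i < 27; i++) fg[i] = nb[i];
  fg[13] = false;
  int compA = 0;
  bool seen[27] = {false};
  for (int i = 0; i < 27; i++) {
    if (!fg[i] || seen[i]) continue;
    compA++;
    if (compA > 1) return false;
    // BFS over 26-adjacency inside the cube
    std::vector<int> stack;
    stack.push_back(i);
    seen[i] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            int ex = cx + dx, ey = cy + dy, ez = cz + dz;
            if (ex < -1 || ex > 1 || ey < -1 || ey > 1 || ez < -1 || ez > 1)
              continue;
            int e = off2idx(ex, ey, ez);
            if (e == c || !fg[e] || seen[e]) continue;
            seen[e] = true;
            stack.push_back(e);
          }
    }
  }
  if (compA != 1) return false;

  // condition B: exactly one 6-component of background within the
  // 18-neighborhood that is 6-adjacent to the center
  bool bg18[27] = {false};
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        int nnz = (dx != 0) + (dy != 0) + (dz != 0);
        if (nnz == 0 || nnz == 3) continue;  // 18-neighborhood
        int i = off2idx(dx, dy, dz);
        bg18[i] = !nb[i];
      }
  int compB = 0;
  bool seenB[27] = {false};
  // start only from 6-neighbors of the center
  const int six[6] = { off2idx(-1,0,0), off2idx(1,0,0), off2idx(0,-1,0),
                       off2idx(0,1,0), off2idx(0,0,-1), off2idx(0,0,1) };
  for (int s = 0; s < 6; s++) {
    int i = six[s];
    if (!bg18[i] || seenB[i]) continue;
    compB++;
    if (compB > 1) return false;
    std::vector<int> stack;
    stack.push_back(i);
    seenB[i] = true;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int cx = c % 3 - 1, cy = (c / 3) % 3 - 1, cz = c / 9 - 1;
      const int d6[6][3] = {{-1,0,0},{1,0,0},{0,-1,0},{0,1,0},{0,0,-1},{0,0,1}};
      for (int k = 0; k < 6; k++) {
        int ex = cx + d6[k][0], ey = cy + d6[k][1], ez = cz + d6[k][2];
        if (ex < -1 || ex > 1 || ey < -1 || ey > 1 || ez < -1 || ez > 1)
          continue;
        int e = off2idx(ex, ey, ez);
        if (!bg18[e] || seenB[e]) continue;
        seenB[e] = true;
        stack.push_back(e);
      }
    }
  }
  return compB == 1;
}

struct QItem {
  double prio;
  long idx;
  bool operator<(const QItem& o) const { return prio > o.prio; }  // min-heap
};

// Topology-preserving sequential thinning: removes simple, non-endpoint
// voxels in increasing priority (distance-transform) order until stable.
// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, NumericVector priority,
                       IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  std::vector<char> fg(n);
  for (long i = 0; i < n; i++) fg[i] = mask[i] ? 1 : 0;

  auto inb = [&](int x, int y, int z) {
    return x >= 0 && x < nx && y >= 0 && y < ny && z >= 0 && z < nz;
  };
  auto at = [&](int x, int y, int z) -> long {
    return (long)x + (long)nx * ((long)y + (long)ny * z);
  };
  auto fill_nb = [&](int x, int y, int z, bool nb[27], int& nfg) {
    nfg = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          int i = off2idx(dx, dy, dz);
          bool v = inb(x + dx, y + dy, z + dz) &&
                   fg[at(x + dx, y + dy, z + dz)];
          nb[i] = v;
          if (v && i != 13) nfg++;
        }
  };

  std::priority_queue<QItem> q;
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        long i = at(x, y, z);
        if (fg[i]) q.push({priority[i], i});
      }

  bool nb[27];
  int nfg;
  while (!q.empty()) {
    long i = q.top().idx;
    q.pop();
    if (!fg[i]) continue;
    int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / ((long)nx * ny));
    fill_nb(x, y, z, nb, nfg);
    if (nfg <= 1) continue;           // endpoint or isolated: keep
    if (!is_simple(nb)) continue;
    fg[i] = 0;                        // remove and revisit the neighborhood
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (!dx && !dy && !dz) continue;
          int ex = x + dx, ey = y + dy, ez = z + dz;
          if (inb(ex, ey, ez) && fg[at(ex, ey, ez)])
            q.push({priority[at(ex, ey, ez)], at(ex, ey, ez)});
        }
  }

  LogicalVector out(n);
  for (long i = 0; i < n; i++) out[i] = fg[i] != 0;
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// 26-connected components of a binary volume (labels 1..k, background 0).
// [[Rcpp::export]]
IntegerVector cpp_components26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  IntegerVector lab(n);
  int next = 0;
  std::vector<long> stack;
  for (long s = 0; s < n; s++) {
    if (!mask[s] || lab[s]) continue;
    next++;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      long c = stack.back(); stack.pop_back();
      int x = (int)(c % nx), y = (int)((c / nx) % ny), z = (int)(c / ((long)nx * ny));
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dx && !dy && !dz) continue;
            int ex = x + dx, ey = y + dy, ez = z + dz;
            if (ex < 0 || ex >= nx || ey < 0 || ey >= ny || ez < 0 || ez >= nz)
              continue;
            long e = (long)ex + (long)nx * ((long)ey + (long)ny * ez);
            if (mask[e] && !lab[e]) {
              lab[e] = next;
              stack.push_back(e);
            }
          }
    }
  }
  lab.attr("dim") = dims;
  return lab;
}

// Count of foreground 26-neighbors for every voxel of a binary volume.
// [[Rcpp::export]]
IntegerVector cpp_neighbor_count26(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  IntegerVector cnt(n);
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        long i = (long)x + (long)nx * ((long)y + (long)ny * z);
        if (!mask[i]) continue;
        int c = 0;
        for (int dz = -1; dz <= 1; dz++)
          for (int dy = -1; dy <= 1; dy++)
            for (int dx = -1; dx <= 1; dx++) {
              if (!dx && !dy && !dz) continue;
              int ex = x + dx, ey = y + dy, ez = z + dz;
              if (ex < 0 || ex >= nx || ey < 0 || ey >= ny || ez < 0 || ez >= nz)
                continue;
              if (mask[(long)ex + (long)nx * ((long)ey + (long)ny * ez)]) c++;
            }
        cnt[i] = c;
      }
  cnt.attr("dim") = dims;
  return cnt;
}

// ---------------------------------------------------------------------------
// Rasterize tubes: points (n x 3, mm world coordinates), per-point radius
// (mm) and 1-based tree-segment index. A voxel is foreground when its
// center lies within the radius of the nearest sampled tube point; ties
// between overlapping tubes go to the most-interior one (max radius-dist),
// then to the lower segment index.
// [[Rcpp::export]]
List cpp_rasterize_tubes(NumericMatrix pts, NumericVector radius,
                         IntegerVector segidx, IntegerVector dims,
                         NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  IntegerVector seg(n);
  NumericVector score(n);
  for (long i = 0; i < n; i++) score[i] = -1e30;

  for (int p = 0; p < pts.nrow(); p++) {
    double px = pts(p, 0), py = pts(p, 1), pz = pts(p, 2), r = radius[p];
    int x0 = (int)std::floor((px - r) / sx - 0.5), x1 = (int)std::ceil((px + r) / sx + 0.5);
    int y0 = (int)std::floor((py - r) / sy - 0.5), y1 = (int)std::ceil((py + r) / sy + 0.5);
    int z0 = (int)std::floor((pz - r) / sz - 0.5), z1 = (int)std::ceil((pz + r) / sz + 0.5);
    if (x0 < 0) x0 = 0; if (y0 < 0) y0 = 0; if (z0 < 0) z0 = 0;
    if (x1 >= nx) x1 = nx - 1; if (y1 >= ny) y1 = ny - 1; if (z1 >= nz) z1 = nz - 1;
    for (int z = z0; z <= z1; z++)
      for (int y = y0; y <= y1; y++)
        for (int x = x0; x <= x1; x++) {
          // voxel center in world mm: (index + 0.5) * spacing
          double dx = (x + 0.5) * sx - px;
          double dy = (y + 0.5) * sy - py;
          double dz = (z + 0.5) * sz - pz;
          double d = std::sqrt(dx * dx + dy * dy + dz * dz);
          if (d > r) continue;
          long i = (long)x + (long)nx * ((long)y + (long)ny * z);
          double s = r - d;
          if (s > score[i] + 1e-12 ||
              (std::fabs(s - score[i]) <= 1e-12 && segidx[p] < seg[i])) {
            score[i] = s;
            seg[i] = segidx[p];
          }
        }
  }
  LogicalVector mask(n);
  for (long i = 0; i < n; i++) mask[i] = seg[i] > 0;
  mask.attr("dim") = dims;
  seg.attr("dim") = dims;
  return List::create(_["mask"] = mask, _["seg"] = seg);
}

// ---------------------------------------------------------------------------
// Assign every mask voxel the id of its nearest centerline voxel
// (spacing-aware Euclidean metric); non-mask voxels get 0. Brute force over
// centerline voxels — centerlines are small.
// [[Rcpp::export]]
IntegerVector cpp_nearest_centerline(LogicalVector mask, IntegerVector dims,
                                     NumericVector spacing,
                                     IntegerMatrix cl_coords,
                                     IntegerVector cl_ids) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const long n = (long)nx * ny * nz;
  const int m = cl_coords.nrow();
  IntegerVector out(n);
  if (m == 0) { out.attr("dim") = dims; return out; }
  std::vector<double> cx(m), cy(m), cz(m);
  for (int j = 0; j < m; j++) {
    cx[j] = cl_coords(j, 0) * spacing[0];
    cy[j] = cl_coords(j, 1) * spacing[1];
    cz[j] = cl_coords(j, 2) * spacing[2];
  }
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        long i = (long)x + (long)nx * ((long)y + (long)ny * z);
        if (!mask[i]) continue;
        double px = x * spacing[0], py = y * spacing[1], pz = z * spacing[2];
        double best = 1e30;
        int bid = 0;
        for (int j = 0; j < m; j++) {
          double dx = px - cx[j], dy = py - cy[j], dz = pz - cz[j];
          double d = dx * dx + dy * dy + dz * dz;
          if (d < best - 1e-12 ||
              (d < best + 1e-12 && cl_ids[j] < bid)) {
            best = d;
            bid = cl_ids[j];
          }
        }
        out[i] = bid;
      }
  out.attr("dim") = dims;
  return out;
}

// ---------------------------------------------------------------------------
// Rotate a patch about its center. rot is the 3x3 voxel-to-voxel rotation in
// world (mm) space; sampling uses the inverse map with trilinear (order=1)
// or nearest-neighbor (order=0) interpolation, fill 0 outside.
// [[Rcpp::export]]
NumericVector cpp_rotate_patch(NumericVector arr, IntegerVector dims,
                               NumericVector spacing, NumericMatrix rot,
                               int order) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out((long)nx * ny * nz);
  double cx = (nx - 1) / 2.0, cy = (ny - 1) / 2.0, cz = (nz - 1) / 2.0;
  // inverse rotation = transpose
  double R[3][3];
  for (int a = 0; a < 3; a++)
    for (int b = 0; b < 3; b++) R[a][b] = rot(b, a);
  auto val = [&](int x, int y, int z) -> double {
    if (x < 0 || x >= nx || y < 0 || y >= ny || z < 0 || z >= nz) return 0.0;
    return arr[(long)x + (long)nx * ((long)y + (long)ny * z)];
  };
  for (int z = 0; z < nz; z++)
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        double wx = (x - cx) * spacing[0];
        double wy = (y - cy) * spacing[1];
        double wz = (z - cz) * spacing[2];
        double sx0 = R[0][0] * wx + R[0][1] * wy + R[0][2] * wz;
        double sy0 = R[1][0] * wx + R[1][1] * wy + R[1][2] * wz;
        double sz0 = R[2][0] * wx + R[2][1] * wy + R[2][2] * wz;
        double fx = sx0 / spacing[0] + cx;
        double fy = sy0 / spacing[1] + cy;
        double fz = sz0 / spacing[2] + cz;
        long o = (long)x + (long)nx * ((long)y + (long)ny * z);
        if (order == 0) {
          int ix = (int)std::lround(fx), iy = (int)std::lround(fy),
              iz = (int)std::lround(fz);
          out[o] = val(ix, iy, iz);
        } else {
          int ix = (int)std::floor(fx), iy = (int)std::floor(fy),
              iz = (int)std::floor(fz);
          double tx = fx - ix, ty = fy - iy, tz = fz - iz;
          double v = 0.0;
          for (int dz = 0; dz <= 1; dz++)
            for (int dy = 0; dy <= 1; dy++)
              for (int dx = 0; dx <= 1; dx++) {
                double w = (dx ? tx : 1 - tx) * (dy ? ty : 1 - ty) *
                           (dz ? tz : 1 - tz);
                if (w > 0) v += w * val(ix + dx, iy + dy, iz + dz);
              }
          out[o] = v;
        }
      }
  out.attr("dim") = dims;
  return out;
}
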