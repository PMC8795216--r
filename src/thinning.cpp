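// 3-D curve skeletonization by distance-ordered homotopic thinning.
//
// Border voxels are deleted in increasing chamfer-distance order, but only
// if deletion preserves topology (simple-point test with 26-connected
// foreground / 6-connected background) and the voxel is not a curve
// endpoint (<= 1 foreground 26-neighbour). The survivors form a
// one-voxel-wide, topology-preserving, well-centered curve skeleton.

#include <Rcpp.h>
#include <queue>
#include <vector>
using namespace Rcpp;

static inline int idx3(int x, int y, int z, int nx, int ny) {
  return x + nx * (y + ny * z);
}

// ---- simple-point test -----------------------------------------------------
// nb: 27 values of the 3x3x3 neighbourhood in (dx,dy,dz) raster order,
// dx fastest; nb[13] is the center (ignored).

static inline int noff(int dx, int dy, int dz) {
  return (dx + 1) + 3 * ((dy + 1) + 3 * (dz + 1));
}

// number of 26-connected components of the foreground among the 26 neighbours
static int fg_components26(const bool *nb) {
  int comp = 0;
  bool seen[27] = {false};
  for (int s = 0; s < 27; ++s) {
    if (s == 13 || !nb[s] || seen[s]) continue;
    ++comp;
    std::vector<int> stack;
    stack.push_back(s);
    seen[s] = true;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int px = p % 3, py = (p / 3) % 3, pz = p / 9;
      for (int q = 0; q < 27; ++q) {
        if (q == 13 || !nb[q] || seen[q]) continue;
        int qx = q % 3, qy = (q / 3) % 3, qz = q / 9;
        int ax = abs(px - qx), ay = abs(py - qy), az = abs(pz - qz);
        if (ax <= 1 && ay <= 1 && az <= 1 && (ax + ay + az) > 0) {
          seen[q] = true;
          stack.push_back(q);
        }
      }
    }
  }
  return comp;
}

// number of 6-connected background components within the 18-neighbourhood
// that touch (are 6-adjacent to) the center
static int bg_components6(const bool *nb) {
  // the 18-neighbourhood: offsets with at most two non-zero coordinates
  bool in18[27];
  for (int s = 0; s < 27; ++s) {
    int sx = s % 3 - 1, sy = (s / 3) % 3 - 1, sz = s / 9 - 1;
    in18[s] = (s != 13) && (abs(sx) + abs(sy) + abs(sz) <= 2);
  }
  bool seen[27] = {false};
  int comp = 0;
  for (int s = 0; s < 27; ++s) {
    if (!in18[s] || nb[s] || seen[s]) continue;
    // flood this background component (6-connectivity inside the 18-set)
    std::vector<int> stack;
    stack.push_back(s);
    seen[s] = true;
    bool touches_center = false;
    while (!stack.empty()) {
      int p = stack.back(); stack.pop_back();
      int px = p % 3, py = (p / 3) % 3, pz = p / 9;
      if (abs(px - 1) + abs(py - 1) + abs(pz - 1) == 1) touches_center = true;
      for (int q = 0; q < 27; ++q) {
        if (!in18[q] || nb[q] || seen[q]) continue;
        int qx = q % 3, qy = (q / 3) % 3, qz = q / 9;
        if (abs(px - qx) + abs(py - qy) + abs(pz - qz) == 1) {
          seen[q] = true;
          stack.push_back(q);
        }
      }
    }
    if (touches_center) ++comp;
  }
  return comp;
}

static inline bool is_simple(const bool *nb) {
  return fg_components26(nb) == 1 && bg_components6(nb) == 1;
}

static void fill_neighbourhood(const std::vector<char> &fg, bool *nb,
                               int x, int y, int z, int nx, int ny, int nz) {
  for (int dz = -1; dz <= 1; ++dz)
    for (int dy = -1; dy <= 1; ++dy)
      for (int dx = -1; dx <= 1; ++dx) {
        int xx = x + dx, yy = y + dy, zz = z + dz;
        bool v = false;
        if (xx >= 0 && xx < nx && yy >= 0 && yy < ny && zz >= 0 && zz < nz)
          v = fg[idx3(xx, yy, zz, nx, ny)] != 0;
        nb[noff(dx, dy, dz)] = v;
      }
}

// ---- chamfer distance transform (3-4-5 weights) ---------------------------

// [[Rcpp::export(name = "cpp_chamfer_dt")]]
NumericVector cpp_chamfer_dt(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  const double BIG = 1e18;
  NumericVector d(n);
  for (int i = 0; i < n; ++i) d[i] = mask[i] ? BIG : 0.0;
  // forward and backward raster passes over the 13 causal neighbours
  int off[13][3] = {
    {-1, 0, 0}, {0, -1, 0}, {0, 0, -1},
    {-1, -1, 0}, {-1, 1, 0}, {-1, 0, -1}, {-1, 0, 1},
    {0, -1, -1}, {0, -1, 1},
    {-1, -1, -1}, {-1, -1, 1}, {-1, 1, -1}, {-1, 1, 1}};
  double w[13];
  for (int k = 0; k < 13; ++k) {
    int a = abs(off[k][0]) + abs(off[k][1]) + abs(off[k][2]);
    w[k] = (a == 1) ? 3.0 : (a == 2 ? 4.0 : 5.0);
  }
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (d[i] == 0.0) continue;
        double best = d[i];
        for (int k = 0; k < 13; ++k) {
          int xx = x + off[k][0], yy = y + off[k][1], zz = z + off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          double c = d[idx3(xx, yy, zz, nx, ny)] + w[k];
          if (c < best) best = c;
        }
        d[i] = best;
      }
  for (int z = nz - 1; z >= 0; --z)
    for (int y = ny - 1; y >= 0; --y)
      for (int x = nx - 1; x >= 0; --x) {
        int i = idx3(x, y, z, nx, ny);
        if (d[i] == 0.0) continue;
        double best = d[i];
        for (int k = 0; k < 13; ++k) {
          int xx = x - off[k][0], yy = y - off[k][1], zz = z - off[k][2];
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          double c = d[idx3(xx, yy, zz, nx, ny)] + w[k];
          if (c < best) best = c;
        }
        d[i] = best;
      }
  for (int i = 0; i < n; ++i) d[i] /= 3.0;  // approximate voxel units
  return d;
}

// ---- thinning --------------------------------------------------------------

// [[Rcpp::export(name = "cpp_thin3d")]]
LogicalVector cpp_thin3d(LogicalVector mask, IntegerVector dim) {
  int nx = dim[0], ny = dim[1], nz = dim[2];
  int n = nx * ny * nz;
  NumericVector dt = cpp_chamfer_dt(mask, dim);
  std::vector<char> fg(n);
  for (int i = 0; i < n; ++i) fg[i] = mask[i] ? 1 : 0;

  typedef std::pair<double, int> QE;  // (distance, linear index), min-first
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  for (int z = 0; z < nz; ++z)
    for (int y = 0; y < ny; ++y)
      for (int x = 0; x < nx; ++x) {
        int i = idx3(x, y, z, nx, ny);
        if (fg[i]) pq.push(QE(dt[i], i));
      }

  bool nb[27];
  while (!pq.empty()) {
    int i = pq.top().second;
    pq.pop();
    if (!fg[i]) continue;
    int x = i % nx, y = (i / nx) % ny, z = i / (nx * ny);
    fill_neighbourhood(fg, nb, x, y, z, nx, ny, nz);
    int nfg = 0;
    for (int s = 0; s < 27; ++s) if (s != 13 && nb[s]) ++nfg;
    if (nfg <= 1) continue;          // curve endpoint or isolated: keep
    if (!is_simple(nb)) continue;    // deletion would change topology
    fg[i] = 0;
    // deletion may render neighbours deletable
    for (int dz = -1; dz <= 1; ++dz)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dx = -1; dx <= 1; ++dx) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            continue;
          int j = idx3(xx, yy, zz, nx, ny);
          if (fg[j]) pq.push(QE(dt[j], j));
        }
  }
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = fg[i] != 0;
  out.attr("dim") = dim;
  return out;
}
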