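// Low-level voxel kernels: Euclidean feature/distance transform, 3-D
// morphological thinning, medial-weighted shortest paths, connected
// components, and arbitrary-point volume sampling. All grids are stored in
// R's column-major order (fastest index first) and all distances are in mm.
#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double INF = std::numeric_limits<double>::infinity();

// ---------------------------------------------------------------------------
// 1-D squared distance transform with feature propagation
// (Felzenszwalb & Huttenlocher lower-envelope algorithm, anisotropic step w).
// f: squared distances at line positions, feat: source voxel ids; results
// overwrite d / dfeat.
static void dt1d(const std::vector<double> &f, const std::vector<int> &feat,
                 double w, std::vector<double> &d, std::vector<int> &dfeat) {
  const int n = (int)f.size();
  std::vector<int> v(n);       // indices of parabolas in lower envelope
  std::vector<double> z(n + 1); // boundaries between parabolas
  int k = -1;
  for (int q = 0; q < n; q++) {
    if (f[q] == INF) continue;
    double xq = q * w;
    if (k < 0) {
      k = 0; v[0] = q; z[0] = -INF; z[1] = INF;
      continue;
    }
    double s;
    for (;;) {
      int p = v[k];
      double xp = p * w;
      s = ((f[q] + xq * xq) - (f[p] + xp * xp)) / (2.0 * (xq - xp));
      if (s <= z[k]) { k--; if (k < 0) break; } else break;
    }
    if (k < 0) { k = 0; v[0] = q; z[0] = -INF; z[1] = INF; }
    else { k++; v[k] = q; z[k] = s; z[k + 1] = INF; }
  }
  if (k < 0) { // no finite parabola on this line
    for (int q = 0; q < n; q++) { d[q] = INF; dfeat[q] = 0; }
    return;
  }
  int j = 0;
  for (int q = 0; q < n; q++) {
    double xq = q * w;
    while (z[j + 1] < xq) j++;
    int p = v[j];
    double dx = xq - p * w;
    d[q] = dx * dx + f[p];
    dfeat[q] = feat[p];
  }
}

// Squared EDT + feature transform from a set of seed voxels.
// seed: logical grid; returns dist (mm) to nearest seed and the 1-based
// linear index of that seed (0 where unreachable).
// [[Rcpp::export]]
List cpp_ft_edt(LogicalVector seed, IntegerVector dims, NumericVector spacing) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<double> D(n);
  std::vector<int> F(n);
  for (R_xlen_t i = 0; i < n; i++) {
    if (seed[i]) { D[i] = 0.0; F[i] = (int)(i + 1); }
    else { D[i] = INF; F[i] = 0; }
  }
  // pass along x
  {
    std::vector<double> f(nx), d(nx); std::vector<int> ft(nx), dft(nx);
    for (int z = 0; z < nz; z++)
      for (int y = 0; y < ny; y++) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + (R_xlen_t)y * nx;
        for (int x = 0; x < nx; x++) { f[x] = D[base + x]; ft[x] = F[base + x]; }
        dt1d(f, ft, spacing[0], d, dft);
        for (int x = 0; x < nx; x++) { D[base + x] = d[x]; F[base + x] = dft[x]; }
      }
  }
  // pass along y
  {
    std::vector<double> f(ny), d(ny); std::vector<int> ft(ny), dft(ny);
    for (int z = 0; z < nz; z++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t base = (R_xlen_t)z * nx * ny + x;
        for (int y = 0; y < ny; y++) { f[y] = D[base + (R_xlen_t)y * nx]; ft[y] = F[base + (R_xlen_t)y * nx]; }
        dt1d(f, ft, spacing[1], d, dft);
        for (int y = 0; y < ny; y++) { D[base + (R_xlen_t)y * nx] = d[y]; F[base + (R_xlen_t)y * nx] = dft[y]; }
      }
  }
  // pass along z
  {
    const R_xlen_t pz = (R_xlen_t)nx * ny;
    std::vector<double> f(nz), d(nz); std::vector<int> ft(nz), dft(nz);
    for (int y = 0; y < ny; y++)
      for (int x = 0; x < nx; x++) {
        R_xlen_t base = (R_xlen_t)y * nx + x;
        for (int z = 0; z < nz; z++) { f[z] = D[base + (R_xlen_t)z * pz]; ft[z] = F[base + (R_xlen_t)z * pz]; }
        dt1d(f, ft, spacing[2], d, dft);
        for (int z = 0; z < nz; z++) { D[base + (R_xlen_t)z * pz] = d[z]; F[base + (R_xlen_t)z * pz] = dft[z]; }
      }
  }
  NumericVector dist(n);
  IntegerVector feat(n);
  for (R_xlen_t i = 0; i < n; i++) {
    dist[i] = (D[i] == INF) ? NA_REAL : std::sqrt(D[i]);
    feat[i] = F[i];
  }
  return List::create(_["dist"] = dist, _["feature"] = feat);
}

// ---------------------------------------------------------------------------
// Topology helpers on the 3x3x3 neighborhood for thinning.
// Local coordinates 0..26, center = 13.

// number of 26-connected components of the object within N26 (center excluded)
static int n26_components(const bool nb[27]) {
  bool seen[27] = {false};
  int comps = 0;
  for (int i = 0; i < 27; i++) {
    if (i == 13 || !nb[i] || seen[i]) continue;
    comps++;
    // BFS
    int stack[27]; int sp = 0; stack[sp++] = i; seen[i] = true;
    while (sp) {
      int c = stack[--sp];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            int x = cx + dx, y = cy + dy, z = cz + dz;
            if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
            int j = x + 3 * y + 9 * z;
            if (j == 13 || j == c || seen[j] || !nb[j]) continue;
            seen[j] = true; stack[sp++] = j;
          }
    }
  }
  return comps;
}

// number of 6-connected background components within N18 that are 6-adjacent
// to the center
static int n6_background_components(const bool nb[27]) {
  // N18: cells with |dx|+|dy|+|dz| <= 2 excluding center
  bool in18[27];
  for (int i = 0; i < 27; i++) {
    int dx = i % 3 - 1, dy = (i / 3) % 3 - 1, dz = i / 9 - 1;
    int manh = std::abs(dx) + std::abs(dy) + std::abs(dz);
    in18[i] = (manh >= 1 && manh <= 2);
  }
  static const int face[6] = {4, 22, 10, 16, 12, 14}; // the 6-neighbors
  bool seen[27] = {false};
  int comps = 0;
  for (int fi = 0; fi < 6; fi++) {
    int i = face[fi];
    if (nb[i] || seen[i]) continue; // background, unvisited
    comps++;
    int stack[27]; int sp = 0; stack[sp++] = i; seen[i] = true;
    while (sp) {
      int c = stack[--sp];
      int cx = c % 3, cy = (c / 3) % 3, cz = c / 9;
      static const int step[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
      for (int s = 0; s < 6; s++) {
        int x = cx + step[s][0], y = cy + step[s][1], z = cz + step[s][2];
        if (x < 0 || x > 2 || y < 0 || y > 2 || z < 0 || z > 2) continue;
        int j = x + 3 * y + 9 * z;
        if (j == 13 || seen[j] || !in18[j] || nb[j]) continue;
        seen[j] = true; stack[sp++] = j;
      }
    }
  }
  return comps;
}

// 3-D thinning to a curve skeleton: iteratively delete simple border points
// (one pass per face direction) while preserving curve endpoints and anchor
// voxels (typically the ridge of the distance transform, which keeps the
// skeleton medial and prevents tubular masks from collapsing to a point).
// [[Rcpp::export]]
LogicalVector cpp_thin(LogicalVector mask, IntegerVector dims,
                       Nullable<LogicalVector> anchor = R_NilValue) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  std::vector<char> M(n);
  for (R_xlen_t i = 0; i < n; i++) M[i] = mask[i] ? 1 : 0;
  std::vector<char> A(n, 0);
  if (anchor.isNotNull()) {
    LogicalVector a(anchor);
    for (R_xlen_t i = 0; i < n; i++) A[i] = a[i] ? 1 : 0;
  }
  const R_xlen_t sx = 1, sy = nx, sz = (R_xlen_t)nx * ny;
  const long dirs[6] = {sx, -sx, sy, -sy, sz, -sz};

  auto getnb = [&](int x, int y, int z, bool nb[27]) {
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          int xx = x + dx, yy = y + dy, zz = z + dz;
          int j = (dx + 1) + 3 * (dy + 1) + 9 * (dz + 1);
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
            nb[j] = false;
          else
            nb[j] = M[(R_xlen_t)zz * sz + (R_xlen_t)yy * sy + xx] != 0;
        }
  };

  bool changed = true;
  std::vector<R_xlen_t> cand;
  while (changed) {
    changed = false;
    for (int d = 0; d < 6; d++) {
      cand.clear();
      for (int z = 0; z < nz; z++)
        for (int y = 0; y < ny; y++)
          for (int x = 0; x < nx; x++) {
            R_xlen_t i = (R_xlen_t)z * sz + (R_xlen_t)y * sy + x;
            if (!M[i]) continue;
            // border in direction d?
            long j = (long)i + dirs[d];
            int xx = x, yy = y, zz = z;
            switch (d) {
              case 0: xx++; break; case 1: xx--; break;
              case 2: yy++; break; case 3: yy--; break;
              case 4: zz++; break; case 5: zz--; break;
            }
            bool bg;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz)
              bg = true;
            else
              bg = !M[j];
            if (bg) cand.push_back(i);
          }
      // sequential deletion keeps topology exact within the pass
      for (size_t c = 0; c < cand.size(); c++) {
        R_xlen_t i = cand[c];
        if (!M[i] || A[i]) continue;
        int x = (int)(i % nx), y = (int)((i / nx) % ny), z = (int)(i / sz);
        bool nb[27];
        getnb(x, y, z, nb);
        int nobj = 0;
        for (int k = 0; k < 27; k++) if (k != 13 && nb[k]) nobj++;
        if (nobj <= 1) continue; // curve endpoint: preserve
        if (n26_components(nb) != 1) continue;
        if (n6_background_components(nb) != 1) continue;
        M[i] = 0;
        changed = true;
      }
    }
  }
  LogicalVector out(n);
  for (R_xlen_t i = 0; i < n; i++) out[i] = M[i] != 0;
  return out;
}

// ---------------------------------------------------------------------------
// Medial-weighted shortest path through a mask. Edge cost into voxel b is
// steplen_mm / (eps + dtb[b]) so routes through wide, central voxels are
// cheap (tracks maximally inscribed spheres). 26-connectivity.
// start/end are 1-based linear indices. Returns the path as 1-based indices,
// start first; empty vector when unreachable.
// [[Rcpp::export]]
IntegerVector cpp_medial_path(LogicalVector mask, NumericVector dtb,
                              IntegerVector dims, NumericVector spacing,
                              int start, int end, double eps) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  std::vector<double> dist(n, INF);
  std::vector<int> prev(n, -1);
  typedef std::pair<double, R_xlen_t> QE;
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  R_xlen_t s0 = start - 1, e0 = end - 1;
  if (!mask[s0] || !mask[e0]) stop("endpoints must lie inside the mask");
  dist[s0] = 0.0;
  pq.push(QE(0.0, s0));
  // precompute neighbor offsets and step lengths
  long off[26]; double slen[26];
  int k = 0;
  for (int dz = -1; dz <= 1; dz++)
    for (int dy = -1; dy <= 1; dy++)
      for (int dx = -1; dx <= 1; dx++) {
        if (!dx && !dy && !dz) continue;
        off[k] = dx + (long)dy * nx + (long)dz * sz;
        double ex = dx * spacing[0], ey = dy * spacing[1], ez = dz * spacing[2];
        slen[k] = std::sqrt(ex * ex + ey * ey + ez * ez);
        k++;
      }
  while (!pq.empty()) {
    QE top = pq.top(); pq.pop();
    R_xlen_t u = top.second;
    if (top.first > dist[u]) continue;
    if (u == e0) break;
    int x = (int)(u % nx), y = (int)((u / nx) % ny), z = (int)(u / sz);
    int k2 = 0;
    for (int dz = -1; dz <= 1; dz++)
      for (int dy = -1; dy <= 1; dy++)
        for (int dx = -1; dx <= 1; dx++) {
          if (!dx && !dy && !dz) continue;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          int kk = k2++;
          if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
          R_xlen_t v = u + off[kk];
          if (!mask[v]) continue;
          double w = slen[kk] / (eps + dtb[v]);
          double nd = dist[u] + w;
          if (nd < dist[v]) {
            dist[v] = nd; prev[v] = (int)u;
            pq.push(QE(nd, v));
          }
        }
  }
  if (dist[e0] == INF) return IntegerVector(0);
  std::vector<int> rev;
  R_xlen_t c = e0;
  while (c != s0) { rev.push_back((int)(c + 1)); c = prev[c]; }
  rev.push_back((int)(s0 + 1));
  IntegerVector path(rev.size());
  for (size_t i = 0; i < rev.size(); i++) path[i] = rev[rev.size() - 1 - i];
  return path;
}

// ---------------------------------------------------------------------------
// 26-connected component labelling. Returns integer labels 1..K (0 = bg).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  IntegerVector lab(n, 0);
  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t i = 0; i < n; i++) {
    if (!mask[i] || lab[i]) continue;
    next++;
    stack.clear(); stack.push_back(i); lab[i] = next;
    while (!stack.empty()) {
      R_xlen_t u = stack.back(); stack.pop_back();
      int x = (int)(u % nx), y = (int)((u / nx) % ny), z = (int)(u / sz);
      for (int dz = -1; dz <= 1; dz++)
        for (int dy = -1; dy <= 1; dy++)
          for (int dx = -1; dx <= 1; dx++) {
            if (!dx && !dy && !dz) continue;
            int xx = x + dx, yy = y + dy, zz = z + dz;
            if (xx < 0 || xx >= nx || yy < 0 || yy >= ny || zz < 0 || zz >= nz) continue;
            R_xlen_t v = u + dx + (R_xlen_t)dy * nx + (R_xlen_t)dz * sz;
            if (mask[v] && !lab[v]) { lab[v] = next; stack.push_back(v); }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Sample a volume at arbitrary world points (mm). Trilinear interpolation or
// nearest neighbor; points outside the grid get `outside`.
// [[Rcpp::export]]
NumericVector cpp_sample_volume(NumericVector vol, IntegerVector dims,
                                NumericVector spacing, NumericVector origin,
                                NumericMatrix pts, double outside,
                                bool nearest) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const R_xlen_t sz = (R_xlen_t)nx * ny;
  const R_xlen_t np = pts.nrow();
  NumericVector out(np);
  for (R_xlen_t p = 0; p < np; p++) {
    double fx = (pts(p, 0) - origin[0]) / spacing[0];
    double fy = (pts(p, 1) - origin[1]) / spacing[1];
    double fz = (pts(p, 2) - origin[2]) / spacing[2];
    if (nearest) {
      int ix = (int)std::lround(fx), iy = (int)std::lround(fy), iz = (int)std::lround(fz);
      if (ix < 0 || ix >= nx || iy < 0 || iy >= ny || iz < 0 || iz >= nz) {
        out[p] = outside;
      } else {
        out[p] = vol[(R_xlen_t)iz * sz + (R_xlen_t)iy * nx + ix];
      }
    } else {
      int x0 = (int)std::floor(fx), y0 = (int)std::floor(fy), z0 = (int)std::floor(fz);
      if (x0 < 0 || x0 + 1 >= nx || y0 < 0 || y0 + 1 >= ny || z0 < 0 || z0 + 1 >= nz) {
        // allow exact upper boundary
        if (fx >= 0 && fx <= nx - 1 && fy >= 0 && fy <= ny - 1 && fz >= 0 && fz <= nz - 1) {
          int ix = std::min((int)std::lround(fx), nx - 1);
          int iy = std::min((int)std::lround(fy), ny - 1);
          int iz = std::min((int)std::lround(fz), nz - 1);
          out[p] = vol[(R_xlen_t)iz * sz + (R_xlen_t)iy * nx + ix];
        } else {
          out[p] = outside;
        }
        continue;
      }
      double tx = fx - x0, ty = fy - y0, tz = fz - z0;
      R_xlen_t b = (R_xlen_t)z0 * sz + (R_xlen_t)y0 * nx + x0;
      double c000 = vol[b],          c100 = vol[b + 1];
      double c010 = vol[b + nx],     c110 = vol[b + nx + 1];
      double c001 = vol[b + sz],     c101 = vol[b + sz + 1];
      double c011 = vol[b + sz + nx], c111 = vol[b + sz + nx + 1];
      double c00 = c000 * (1 - tx) + c100 * tx;
      double c10 = c010 * (1 - tx) + c110 * tx;
      double c01 = c001 * (1 - tx) + c101 * tx;
      double c11 = c011 * (1 - tx) + c111 * tx;
      double c0 = c00 * (1 - ty) + c10 * ty;
      double c1 = c01 * (1 - ty) + c11 * ty;
      out[p] = c0 * (1 - tz) + c1 * tz;
    }
  }
  return out;
}
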