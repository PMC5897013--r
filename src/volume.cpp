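#include <Rcpp.h>
#include <cmath>
#include <map>
#include <queue>
#include <vector>
using namespace Rcpp;

// Binary volume machinery: 6-connected region growing, ball-kernel
// morphology, cavity filling, isosurface extraction over a consistent
// 6-tetrahedra cube decomposition, and parity-count voxelization.

static inline long long lidx(int i, int j, int k, int nx, int ny) {
  return (long long)i + (long long)nx * ((long long)j + (long long)ny * k);
}

// [[Rcpp::export]]
LogicalVector region_grow_cpp(NumericVector vol, IntegerVector dims,
                              double threshold, IntegerVector seed) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  LogicalVector out(vol.size());
  std::vector<char> vis((size_t)vol.size(), 0);
  int si = seed[0] - 1, sj = seed[1] - 1, sk = seed[2] - 1;
  long long s = lidx(si, sj, sk, nx, ny);
  if (vol[s] < threshold) return out; // seed below threshold: empty
  std::queue<std::array<int, 3>> q;
  q.push({si, sj, sk});
  vis[s] = 1;
  const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    auto c = q.front(); q.pop();
    out[lidx(c[0], c[1], c[2], nx, ny)] = true;
    for (int m = 0; m < 6; ++m) {
      int i = c[0] + d[m][0], j = c[1] + d[m][1], k = c[2] + d[m][2];
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
      long long l = lidx(i, j, k, nx, ny);
      if (vis[l] || vol[l] < threshold) continue;
      vis[l] = 1;
      q.push({i, j, k});
    }
  }
  return out;
}

// Ball-kernel dilation (dilate = true) or erosion. Out-of-volume voxels
// count as background, so erosion shrinks at the volume border.
// [[Rcpp::export]]
LogicalVector morph_ball_cpp(LogicalVector mask, IntegerVector dims,
                             int radius, bool dilate) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<std::array<int, 3>> off;
  for (int a = -radius; a <= radius; ++a)
    for (int b = -radius; b <= radius; ++b)
      for (int c = -radius; c <= radius; ++c)
        if (a * a + b * b + c * c <= radius * radius)
          off.push_back({a, b, c});
  LogicalVector out(mask.size());
  for (int k = 0; k < nz; ++k)
    for (int j = 0; j < ny; ++j)
      for (int i = 0; i < nx; ++i) {
        bool acc = !dilate;
        for (auto& o : off) {
          int ii = i + o[0], jj = j + o[1], kk = k + o[2];
          bool v = false;
          if (ii >= 0 && jj >= 0 && kk >= 0 && ii < nx && jj < ny && kk < nz)
            v = mask[lidx(ii, jj, kk, nx, ny)];
          if (dilate) { if (v) { acc = true; break; } }
          else        { if (!v) { acc = false; break; } }
        }
        out[lidx(i, j, k, nx, ny)] = acc;
      }
  return out;
}

// Background components not reachable from the volume border (6-conn)
// are enclosed cavities; relabel them foreground.
// [[Rcpp::export]]
LogicalVector hollow_fill_cpp(LogicalVector mask, IntegerVector dims) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  std::vector<char> outside((size_t)mask.size(), 0);
  std::queue<std::array<int, 3>> q;
  auto push_bg = [&](int i, int j, int k) {
    long long l = lidx(i, j, k, nx, ny);
    if (!mask[l] && !outside[l]) { outside[l] = 1; q.push({i, j, k}); }
  };
  for (int j = 0; j < ny; ++j)
    for (int k = 0; k < nz; ++k) { push_bg(0, j, k); push_bg(nx - 1, j, k); }
  for (int i = 0; i < nx; ++i)
    for (int k = 0; k < nz; ++k) { push_bg(i, 0, k); push_bg(i, ny - 1, k); }
  for (int i = 0; i < nx; ++i)
    for (int j = 0; j < ny; ++j) { push_bg(i, j, 0); push_bg(i, j, nz - 1); }
  const int d[6][3] = {{1,0,0},{-1,0,0},{0,1,0},{0,-1,0},{0,0,1},{0,0,-1}};
  while (!q.empty()) {
    auto c = q.front(); q.pop();
    for (int m = 0; m < 6; ++m) {
      int i = c[0] + d[m][0], j = c[1] + d[m][1], k = c[2] + d[m][2];
      if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) continue;
      push_bg(i, j, k);
    }
  }
  LogicalVector out(mask.size());
  for (R_xlen_t l = 0; l < mask.size(); ++l) out[l] = mask[l] || !outside[l];
  return out;
}

// Isosurface of a scalar field at a given level. Each cell between
// eight voxel centers is split into six tetrahedra sharing the main
// diagonal; the split is translation-invariant, so shared cell faces
// are cut by the same diagonal from both sides and the mesh is
// edge-manifold and watertight. The volume is treated as padded with a
// below-iso layer, so the surface always closes. Vertices sit on
// voxel-center edges at the linear interpolation of the crossing.
// [[Rcpp::export]]
List marching_tets_cpp(NumericVector field, IntegerVector dims,
                       NumericVector spacing, NumericVector origin,
                       double iso) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  auto val = [&](int i, int j, int k) -> double {
    if (i < 0 || j < 0 || k < 0 || i >= nx || j >= ny || k >= nz) return 0.0;
    return field[lidx(i, j, k, nx, ny)];
  };
  // corner offsets of a cell, classic ordering; main diagonal 0-6
  const int co[8][3] = {{0,0,0},{1,0,0},{1,1,0},{0,1,0},
                        {0,0,1},{1,0,1},{1,1,1},{0,1,1}};
  const int tets[6][4] = {{0,5,1,6},{0,1,2,6},{0,2,3,6},
                          {0,3,7,6},{0,7,4,6},{0,4,5,6}};
  const long long NXP = nx + 2, NYP = ny + 2;
  auto gid = [&](int i, int j, int k) -> long long {
    return (long long)(i + 1) + NXP * ((long long)(j + 1) + NYP * (k + 1));
  };
  std::map<std::pair<long long, long long>, int> vmap;
  std::vector<double> vx, vy, vz;
  std::vector<int> f0, f1, f2;

  auto edge_vert = [&](const int a[3], const int b[3]) -> int {
    long long ga = gid(a[0], a[1], a[2]), gb = gid(b[0], b[1], b[2]);
    auto key = std::make_pair(std::min(ga, gb), std::max(ga, gb));
    auto it = vmap.find(key);
    if (it != vmap.end()) return it->second;
    double fa = val(a[0], a[1], a[2]), fb = val(b[0], b[1], b[2]);
    double t = (fa == fb) ? 0.5 : (iso - fa) / (fb - fa);
    if (t < 0) t = 0; else if (t > 1) t = 1;
    double mx = a[0] + t * (b[0] - a[0]) + 0.5; // +0.5: voxel centers
    double my = a[1] + t * (b[1] - a[1]) + 0.5;
    double mz = a[2] + t * (b[2] - a[2]) + 0.5;
    vx.push_back(origin[0] + spacing[0] * mx);
    vy.push_back(origin[1] + spacing[1] * my);
    vz.push_back(origin[2] + spacing[2] * mz);
    int id = (int)vx.size() - 1;
    vmap[key] = id;
    return id;
  };

  auto emit = [&](int a, int b, int c, const double in_c[3],
                  const double out_c[3]) {
    // orient so the normal points from inside (foreground) outward
    double ax = vx[a], ay = vy[a], az = vz[a];
    double ux = vx[b] - ax, uy = vy[b] - ay, uz = vz[b] - az;
    double wx = vx[c] - ax, wy = vy[c] - ay, wz = vz[c] - az;
    double nxn = uy * wz - uz * wy;
    double nyn = uz * wx - ux * wz;
    double nzn = ux * wy - uy * wx;
    double dx = out_c[0] - in_c[0], dy = out_c[1] - in_c[1],
           dz = out_c[2] - in_c[2];
    if (nxn * dx + nyn * dy + nzn * dz < 0) std::swap(b, c);
    f0.push_back(a); f1.push_back(b); f2.push_back(c);
  };

  for (int k = -1; k < nz; ++k)
    for (int j = -1; j < ny; ++j)
      for (int i = -1; i < nx; ++i) {
        bool cv[8];
        int cc[8][3], csum = 0;
        for (int m = 0; m < 8; ++m) {
          cc[m][0] = i + co[m][0]; cc[m][1] = j + co[m][1];
          cc[m][2] = k + co[m][2];
          cv[m] = val(cc[m][0], cc[m][1], cc[m][2]) >= iso;
          csum += cv[m] ? 1 : 0;
        }
        if (csum == 0 || csum == 8) continue;
        for (int t = 0; t < 6; ++t) {
          int vi[4] = {tets[t][0], tets[t][1], tets[t][2], tets[t][3]};
          int ins[4], nin = 0, outs[4], nout = 0;
          for (int m = 0; m < 4; ++m) {
            if (cv[vi[m]]) ins[nin++] = vi[m]; else outs[nout++] = vi[m];
          }
          if (nin == 0 || nin == 4) continue;
          double in_c[3] = {0, 0, 0}, out_c[3] = {0, 0, 0};
          for (int m = 0; m < nin; ++m)
            for (int d = 0; d < 3; ++d)
              in_c[d] += (cc[ins[m]][d] + 0.5) * spacing[d] + origin[d];
          for (int m = 0; m < nout; ++m)
            for (int d = 0; d < 3; ++d)
              out_c[d] += (cc[outs[m]][d] + 0.5) * spacing[d] + origin[d];
          for (int d = 0; d < 3; ++d) { in_c[d] /= nin; out_c[d] /= nout; }
          if (nin == 1) {
            int a = edge_vert(cc[ins[0]], cc[outs[0]]);
            int b = edge_vert(cc[ins[0]], cc[outs[1]]);
            int c = edge_vert(cc[ins[0]], cc[outs[2]]);
            emit(a, b, c, in_c, out_c);
          } else if (nin == 3) {
            int a = edge_vert(cc[outs[0]], cc[ins[0]]);
            int b = edge_vert(cc[outs[0]], cc[ins[1]]);
            int c = edge_vert(cc[outs[0]], cc[ins[2]]);
            emit(a, b, c, in_c, out_c);
          } else { // 2-2: quad split into two triangles
            int a = edge_vert(cc[ins[0]], cc[outs[0]]);
            int b = edge_vert(cc[ins[0]], cc[outs[1]]);
            int c = edge_vert(cc[ins[1]], cc[outs[1]]);
            int d = edge_vert(cc[ins[1]], cc[outs[0]]);
            emit(a, b, c, in_c, out_c);
            emit(a, c, d, in_c, out_c);
          }
        }
      }

  NumericMatrix V(vx.size(), 3);
  for (size_t m = 0; m < vx.size(); ++m) {
    V(m, 0) = vx[m]; V(m, 1) = vy[m]; V(m, 2) = vz[m];
  }
  IntegerMatrix F(f0.size(), 3);
  for (size_t m = 0; m < f0.size(); ++m) {
    F(m, 0) = f0[m] + 1; F(m, 1) = f1[m] + 1; F(m, 2) = f2[m] + 1;
  }
  return List::create(_["vertices"] = V, _["faces"] = F);
}

// Solid voxelization by z-column parity counting. Voxel (i,j,k)
// (1-based in R, 0-based here) has center origin + spacing*(idx+0.5).
// Sample columns are jittered by a tiny irrational offset to avoid
// hitting triangle edges exactly.
// [[Rcpp::export]]
LogicalVector voxelize_cpp(NumericMatrix verts, IntegerMatrix faces,
                           IntegerVector dims, NumericVector spacing,
                           NumericVector origin) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double jx = 1.013e-5, jy = 2.127e-5;
  std::vector<std::vector<double>> cross((size_t)nx * ny);
  for (int t = 0; t < faces.nrow(); ++t) {
    int a = faces(t, 0) - 1, b = faces(t, 1) - 1, c = faces(t, 2) - 1;
    double ax = verts(a, 0), ay = verts(a, 1), az = verts(a, 2);
    double bx = verts(b, 0), by = verts(b, 1), bz = verts(b, 2);
    double cx = verts(c, 0), cy = verts(c, 1), cz = verts(c, 2);
    double xlo = std::min({ax, bx, cx}), xhi = std::max({ax, bx, cx});
    double ylo = std::min({ay, by, cy}), yhi = std::max({ay, by, cy});
    int ilo = std::max(0, (int)std::ceil((xlo - origin[0]) / spacing[0] - 0.5 - jx));
    int ihi = std::min(nx - 1, (int)std::floor((xhi - origin[0]) / spacing[0] - 0.5 - jx) + 1);
    int jlo = std::max(0, (int)std::ceil((ylo - origin[1]) / spacing[1] - 0.5 - jy));
    int jhi = std::min(ny - 1, (int)std::floor((yhi - origin[1]) / spacing[1] - 0.5 - jy) + 1);
    for (int i = ilo; i <= ihi; ++i) {
      double px = origin[0] + spacing[0] * (i + 0.5 + jx);
      for (int j = jlo; j <= jhi; ++j) {
        double py = origin[1] + spacing[1] * (j + 0.5 + jy);
        double d1 = (bx - ax) * (py - ay) - (by - ay) * (px - ax);
        double d2 = (cx - bx) * (py - by) - (cy - by) * (px - bx);
        double d3 = (ax - cx) * (py - cy) - (ay - cy) * (px - cx);
        bool neg = (d1 < 0) || (d2 < 0) || (d3 < 0);
        bool pos = (d1 > 0) || (d2 > 0) || (d3 > 0);
        if (neg && pos) continue; // outside in xy
        double den = d1 + d2 + d3;
        if (den == 0) continue;   // degenerate in xy projection
        double z = (d2 * az + d3 * bz + d1 * cz) / den;
        cross[(size_t)i + (size_t)nx * j].push_back(z);
      }
    }
  }
  LogicalVector out((R_xlen_t)nx * ny * nz);
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i) {
      auto& zs = cross[(size_t)i + (size_t)nx * j];
      if (zs.empty()) continue;
      std::sort(zs.begin(), zs.end());
      for (int k = 0; k < nz; ++k) {
        double zc = origin[2] + spacing[2] * (k + 0.5);
        int below = (int)(std::lower_bound(zs.begin(), zs.end(), zc) -
                          zs.begin());
        if (below % 2 == 1)
          out[lidx(i, j, k, nx, ny)] = true;
      }
    }
  return out;
}
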