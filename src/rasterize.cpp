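#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Perspective rasterizer used for silhouettes, depth buffers and
// normal-dot maps. Vertices arrive already transformed into camera
// coordinates (+z along the viewing ray, +y up, +x = ray x up).
// Screen mapping: u = width/2 + x*f/z, v = height/2 - y*f/z, pixel
// (i, j) (1-based row/col) has center (u, v) = (j - 0.5, i - 0.5).
//
// Coverage rule: a pixel belongs to a triangle iff its center lies
// strictly inside, or on a top/left edge (deterministic tie-break).
// No back-face culling: silhouettes must be robust to flipped faces.

static inline double edge_fn(double ax, double ay, double bx, double by,
                             double px, double py) {
  return (bx - ax) * (py - ay) - (by - ay) * (px - ax);
}

// [[Rcpp::export]]
List rasterize_mesh_cpp(NumericMatrix verts_cam, IntegerMatrix faces,
                        NumericMatrix fnorm_cam, double f,
                        int width, int height) {
  if (width <= 0 || height <= 0)
    stop("zero-area image");
  const int nf = faces.nrow();
  NumericMatrix depth(height, width);
  IntegerMatrix face_id(height, width);
  NumericMatrix ndot(height, width);
  const double INF = std::numeric_limits<double>::infinity();
  std::fill(depth.begin(), depth.end(), INF);

  const double cx = width / 2.0, cy = height / 2.0;
  const double zmin = 1e-9;

  for (int t = 0; t < nf; ++t) {
    int i0 = faces(t, 0), i1 = faces(t, 1), i2 = faces(t, 2);
    double z0 = verts_cam(i0, 2), z1 = verts_cam(i1, 2), z2 = verts_cam(i2, 2);
    if (z0 <= zmin || z1 <= zmin || z2 <= zmin) continue; // behind camera
    double u0 = cx + verts_cam(i0, 0) * f / z0;
    double v0 = cy - verts_cam(i0, 1) * f / z0;
    double u1 = cx + verts_cam(i1, 0) * f / z1;
    double v1 = cy - verts_cam(i1, 1) * f / z1;
    double u2 = cx + verts_cam(i2, 0) * f / z2;
    double v2 = cy - verts_cam(i2, 1) * f / z2;

    double area = edge_fn(u0, v0, u1, v1, u2, v2);
    if (area == 0.0) continue;
    if (area < 0) { // force positive orientation in (u, v)
      std::swap(u1, u2); std::swap(v1, v2); std::swap(z1, z2);
      area = -area;
    }

    int jlo = std::max(0, (int)std::floor(std::min({u0, u1, u2}) - 0.5));
    int jhi = std::min(width - 1, (int)std::ceil(std::max({u0, u1, u2}) - 0.5));
    int ilo = std::max(0, (int)std::floor(std::min({v0, v1, v2}) - 0.5));
    int ihi = std::min(height - 1, (int)std::ceil(std::max({v0, v1, v2}) - 0.5));
    if (jlo > jhi || ilo > ihi) continue;

    // top/left flags per edge (v grows downward)
    auto topleft = [](double ax, double ay, double bx, double by) {
      double dx = bx - ax, dy = by - ay;
      return (dy < 0) || (dy == 0 && dx > 0);
    };
    bool tl0 = topleft(u0, v0, u1, v1);
    bool tl1 = topleft(u1, v1, u2, v2);
    bool tl2 = topleft(u2, v2, u0, v0);

    double nx = fnorm_cam(t, 0), ny = fnorm_cam(t, 1), nz = fnorm_cam(t, 2);

    for (int i = ilo; i <= ihi; ++i) {
      double py = i + 0.5;
      for (int j = jlo; j <= jhi; ++j) {
        double px = j + 0.5;
        double e0 = edge_fn(u0, v0, u1, v1, px, py);
        double e1 = edge_fn(u1, v1, u2, v2, px, py);
        double e2 = edge_fn(u2, v2, u0, v0, px, py);
        bool in = (e0 > 0 || (e0 == 0 && tl0)) &&
                  (e1 > 0 || (e1 == 0 && tl1)) &&
                  (e2 > 0 || (e2 == 0 && tl2));
        if (!in) continue;
        double l0 = e1 / area, l1 = e2 / area, l2 = e0 / area;
        double invz = l0 / z0 + l1 / z1 + l2 / z2;
        if (invz <= 0) continue;
        double z = 1.0 / invz;
        if (z < depth(i, j)) {
          depth(i, j) = z;
          face_id(i, j) = t + 1;
          // view ray through this pixel in camera coordinates
          double rx = (px - cx) / f, ry = (cy - py) / f, rz = 1.0;
          double rn = std::sqrt(rx * rx + ry * ry + rz * rz);
          ndot(i, j) = -(rx * nx + ry * ny + rz * nz) / rn;
        }
      }
    }
  }
  return List::create(_["depth"] = depth, _["face"] = face_id,
                      _["normal_dot"] = ndot);
}

// Orthographic rasterizer for UV-space triangles: fills a res x res
// texel grid with the face id and barycentric coordinates of the
// triangle covering each texel center. UVs in [0,1]^2; texel (i, j)
// center maps to uv * res = (j - 0.5, i - 0.5) with v up = row down
// kept consistent with the atlas convention (row 1 = v near 1).

// [[Rcpp::export]]
List rasterize_uv_cpp(NumericMatrix uv, IntegerMatrix faces,
                      IntegerVector face_ids, int res) {
  IntegerMatrix fid(res, res);
  NumericMatrix b0(res, res), b1(res, res), b2(res, res);
  const int nf = faces.nrow();
  for (int t = 0; t < nf; ++t) {
    double u0 = uv(faces(t, 0), 0) * res, v0 = (1.0 - uv(faces(t, 0), 1)) * res;
    double u1 = uv(faces(t, 1), 0) * res, v1 = (1.0 - uv(faces(t, 1), 1)) * res;
    double u2 = uv(faces(t, 2), 0) * res, v2 = (1.0 - uv(faces(t, 2), 1)) * res;
    double area = edge_fn(u0, v0, u1, v1, u2, v2);
    bool swapped = false;
    if (area == 0.0) continue;
    if (area < 0) {
      std::swap(u1, u2); std::swap(v1, v2);
      area = -area; swapped = true;
    }
    int jlo = std::max(0, (int)std::floor(std::min({u0, u1, u2}) - 0.5));
    int jhi = std::min(res - 1, (int)std::ceil(std::max({u0, u1, u2}) - 0.5));
    int ilo = std::max(0, (int)std::floor(std::min({v0, v1, v2}) - 0.5));
    int ihi = std::min(res - 1, (int)std::ceil(std::max({v0, v1, v2}) - 0.5));
    for (int i = ilo; i <= ihi; ++i) {
      double py = i + 0.5;
      for (int j = jlo; j <= jhi; ++j) {
        double px = j + 0.5;
        double e0 = edge_fn(u0, v0, u1, v1, px, py);
        double e1 = edge_fn(u1, v1, u2, v2, px, py);
        double e2 = edge_fn(u2, v2, u0, v0, px, py);
        if (e0 < 0 || e1 < 0 || e2 < 0) continue;
        double l0 = e1 / area, l1 = e2 / area, l2 = e0 / area;
        fid(i, j) = face_ids[t];
        if (swapped) std::swap(l1, l2); // undo vertex swap
        b0(i, j) = l0; b1(i, j) = l1; b2(i, j) = l2;
      }
    }
  }
  return List::create(_["face"] = fid, _["b0"] = b0, _["b1"] = b1,
                      _["b2"] = b2);
}

// Fused fast path for the refinement stages: rasterize the mesh, walk
// the silhouette boundary and average the photograph's distance field
// under it, all without allocating R-side buffers. Returns -1 when the
// silhouette is empty.
// [[Rcpp::export]]
double silhouette_cost_cpp(NumericMatrix verts_cam, IntegerMatrix faces,
                           double f, int width, int height,
                           NumericMatrix D) {
  const int nf = faces.nrow();
  static std::vector<char> cov;
  cov.assign((size_t)width * height, 0);
  int bb_ilo = height, bb_ihi = -1, bb_jlo = width, bb_jhi = -1;
  const double cx = width / 2.0, cy = height / 2.0;
  const double zmin = 1e-9;
  for (int t = 0; t < nf; ++t) {
    int i0 = faces(t, 0), i1 = faces(t, 1), i2 = faces(t, 2);
    double z0 = verts_cam(i0, 2), z1 = verts_cam(i1, 2), z2 = verts_cam(i2, 2);
    if (z0 <= zmin || z1 <= zmin || z2 <= zmin) continue;
    double u0 = cx + verts_cam(i0, 0) * f / z0;
    double v0 = cy - verts_cam(i0, 1) * f / z0;
    double u1 = cx + verts_cam(i1, 0) * f / z1;
    double v1 = cy - verts_cam(i1, 1) * f / z1;
    double u2 = cx + verts_cam(i2, 0) * f / z2;
    double v2 = cy - verts_cam(i2, 1) * f / z2;
    double area = edge_fn(u0, v0, u1, v1, u2, v2);
    if (area == 0.0) continue;
    if (area < 0) { std::swap(u1, u2); std::swap(v1, v2); }
    int jlo = std::max(0, (int)std::floor(std::min({u0, u1, u2}) - 0.5));
    int jhi = std::min(width - 1, (int)std::ceil(std::max({u0, u1, u2}) - 0.5));
    int ilo = std::max(0, (int)std::floor(std::min({v0, v1, v2}) - 0.5));
    int ihi = std::min(height - 1, (int)std::ceil(std::max({v0, v1, v2}) - 0.5));
    // same top/left tie rule as the full rasterizer so costs agree with
    // silhouette_distance on a re-render, ties included
    auto topleft = [](double ax, double ay, double bx, double by) {
      double dx = bx - ax, dy = by - ay;
      return (dy < 0) || (dy == 0 && dx > 0);
    };
    bool tl0 = topleft(u0, v0, u1, v1);
    bool tl1 = topleft(u1, v1, u2, v2);
    bool tl2 = topleft(u2, v2, u0, v0);
    if (ilo < bb_ilo) bb_ilo = ilo;
    if (ihi > bb_ihi) bb_ihi = ihi;
    if (jlo < bb_jlo) bb_jlo = jlo;
    if (jhi > bb_jhi) bb_jhi = jhi;
    for (int i = ilo; i <= ihi; ++i) {
      double py = i + 0.5;
      for (int j = jlo; j <= jhi; ++j) {
        if (cov[(size_t)j * height + i]) continue;
        double px = j + 0.5;
        double e0 = edge_fn(u0, v0, u1, v1, px, py);
        double e1 = edge_fn(u1, v1, u2, v2, px, py);
        double e2 = edge_fn(u2, v2, u0, v0, px, py);
        bool in = (e0 > 0 || (e0 == 0 && tl0)) &&
                  (e1 > 0 || (e1 == 0 && tl1)) &&
                  (e2 > 0 || (e2 == 0 && tl2));
        if (in) cov[(size_t)j * height + i] = 1;
      }
    }
  }
  double acc = 0.0;
  long n = 0;
  if (bb_ihi < 0) return -1.0;
  for (int j = bb_jlo; j <= bb_jhi; ++j) {
    for (int i = bb_ilo; i <= bb_ihi; ++i) {
      if (!cov[(size_t)j * height + i]) continue;
      bool b = (i == 0) || (i == height - 1) || (j == 0) || (j == width - 1) ||
               !cov[(size_t)j * height + i - 1] ||
               !cov[(size_t)j * height + i + 1] ||
               !cov[(size_t)(j - 1) * height + i] ||
               !cov[(size_t)(j + 1) * height + i];
      if (b) { acc += D(i, j); ++n; }
    }
  }
  if (n == 0) return -1.0;
  return acc / n;
}
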