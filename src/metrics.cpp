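#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

// Silhouette matching primitives: boundary extraction, exact Euclidean
// distance transform to the boundary (Felzenszwalb & Huttenlocher
// two-pass lower-envelope algorithm), and the exhaustive 1-degree
// rotation search used by the coarse pose stage.

// [[Rcpp::export]]
IntegerMatrix boundary_pixels_cpp(LogicalMatrix img) {
  const int h = img.nrow(), w = img.ncol();
  std::vector<int> rr, cc;
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) {
      if (!img(i, j)) continue;
      bool b = (i == 0) || (i == h - 1) || (j == 0) || (j == w - 1) ||
               !img(i - 1, j) || !img(i + 1, j) ||
               !img(i, j - 1) || !img(i, j + 1);
      if (b) { rr.push_back(i + 1); cc.push_back(j + 1); }
    }
  }
  IntegerMatrix out(rr.size(), 2);
  for (size_t k = 0; k < rr.size(); ++k) { out(k, 0) = rr[k]; out(k, 1) = cc[k]; }
  return out;
}

// seeds use a large finite sentinel instead of infinity so the
// lower-envelope intersections stay well defined
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (k > 0 && s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Squared-EDT seeded at the boundary pixels of img; returns Euclidean
// distance [px] of every pixel to its nearest boundary pixel.
// [[Rcpp::export]]
NumericMatrix distance_field_cpp(LogicalMatrix img) {
  const int h = img.nrow(), w = img.ncol();
  const double BIG = 1e18;
  IntegerMatrix bp = boundary_pixels_cpp(img);
  if (bp.nrow() == 0) stop("empty silhouette: no boundary pixels");
  NumericMatrix g(h, w);
  std::fill(g.begin(), g.end(), BIG);
  for (int k = 0; k < bp.nrow(); ++k) g(bp(k, 0) - 1, bp(k, 1) - 1) = 0.0;

  // pass 1: columns
  std::vector<double> f(h), d(h);
  for (int j = 0; j < w; ++j) {
    for (int i = 0; i < h; ++i) f[i] = g(i, j);
    dt1d(f, d, h);
    for (int i = 0; i < h; ++i) g(i, j) = d[i];
  }
  // pass 2: rows
  std::vector<double> f2(w), d2(w);
  for (int i = 0; i < h; ++i) {
    for (int j = 0; j < w; ++j) f2[j] = g(i, j);
    dt1d(f2, d2, w);
    for (int j = 0; j < w; ++j) g(i, j) = std::sqrt(d2[j]);
  }
  return g;
}

// bilinear sample at a continuous (row, col) position (pixel i holds
// its value at coordinate i); coordinates clamped to the border
static inline double sample_clamped(const NumericMatrix& D, double row,
                                    double col) {
  const int h = D.nrow(), w = D.ncol();
  if (row < 1) row = 1; else if (row > h) row = h;
  if (col < 1) col = 1; else if (col > w) col = w;
  int i0 = (int)std::floor(row); if (i0 > h - 1) i0 = h - 1;
  int j0 = (int)std::floor(col); if (j0 > w - 1) j0 = w - 1;
  double fr = row - i0, fc = col - j0;
  double v00 = D(i0 - 1, j0 - 1), v01 = D(i0 - 1, j0);
  double v10 = D(i0, j0 - 1), v11 = D(i0, j0);
  return (1 - fr) * ((1 - fc) * v00 + fc * v01) +
         fr * ((1 - fc) * v10 + fc * v11);
}

// Exhaustive 1-degree rotation search: boundary points of the render are
// rotated (in screen coordinates, y up) about the render centroid g_r,
// translated onto the photo centroid g_t, and the photo's boundary
// distance field is averaged under them. Returns (cost, alpha_deg).
//
// Branch-and-bound variant: an angle's accumulation aborts as soon as
// its partial sum provably exceeds min(candidate's own best, thr) -- the
// summands are non-negative, so the reported minimum is exact whenever
// it is <= thr, and a lower bound otherwise.
static NumericVector alpha_search_pruned(const NumericMatrix& D,
                                         const NumericVector& gt,
                                         const NumericMatrix& bpts,
                                         const NumericVector& gr,
                                         double thr) {
  const int n = bpts.nrow();
  if (n == 0) stop("empty render boundary");
  std::vector<double> sx(n), sy(n);
  for (int k = 0; k < n; ++k) {
    sx[k] = bpts(k, 1) - gr[1];      // screen x = +col
    sy[k] = gr[0] - bpts(k, 0);      // screen y = -row
  }
  double best = std::numeric_limits<double>::infinity();
  int best_a = 0;
  for (int a = 0; a < 360; ++a) {
    double ca = std::cos(a * M_PI / 180.0), sa = std::sin(a * M_PI / 180.0);
    double acc = 0.0;
    double cut = std::min(best, thr) * n;
    bool aborted = false;
    for (int k = 0; k < n; ++k) {
      double rx = ca * sx[k] - sa * sy[k];
      double ry = sa * sx[k] + ca * sy[k];
      acc += sample_clamped(D, gt[0] - ry, gt[1] + rx);
      if (acc > cut && (k & 15) == 15) { aborted = true; break; }
    }
    if (aborted) continue;
    double cost = acc / n;
    if (cost < best) { best = cost; best_a = a; }
  }
  return NumericVector::create(best, (double)best_a);
}

// [[Rcpp::export]]
NumericVector alpha_search_cpp(NumericMatrix D, NumericVector gt,
                               NumericMatrix bpts, NumericVector gr) {
  return alpha_search_pruned(D, gt, bpts, gr,
                             std::numeric_limits<double>::infinity());
}

// Batch version over a list of candidate boundaries; one row of
// (cost, alpha_deg) per candidate; empty candidates get cost Inf.
// For ranking thousands of candidates the boundary may be subsampled
// uniformly to at most max_pts pixels (0 = no cap): the cost is a mean,
// so a uniform subsample estimates it unbiasedly, and the winners are
// re-scored by the refinement stages on full boundaries anyway.
// When n_keep > 0 the search additionally prunes with the running
// n_keep-th best cost: the best n_keep candidates and their costs are
// exact; entries that provably cannot enter that set may carry a lower
// bound instead of the exact cost.
// [[Rcpp::export]]
NumericMatrix alpha_search_batch_cpp(NumericMatrix D, NumericVector gt,
                                     List bpts_list, NumericMatrix grs,
                                     int max_pts = 0, int n_keep = 0) {
  const int nc = bpts_list.size();
  NumericMatrix out(nc, 2);
  std::vector<double> kept;   // running best costs, ascending
  const double INF = std::numeric_limits<double>::infinity();
  for (int c = 0; c < nc; ++c) {
    RObject o = bpts_list[c];
    if (o.isNULL()) {
      out(c, 0) = INF;
      out(c, 1) = 0.0;
      continue;
    }
    NumericMatrix bp = as<NumericMatrix>(o);
    if (bp.nrow() == 0) {
      out(c, 0) = INF;
      out(c, 1) = 0.0;
      continue;
    }
    if (max_pts > 0 && bp.nrow() > max_pts) {
      int n = bp.nrow();
      NumericMatrix sub(max_pts, 2);
      for (int k = 0; k < max_pts; ++k) {
        int i = (int)((long long)k * n / max_pts);
        sub(k, 0) = bp(i, 0);
        sub(k, 1) = bp(i, 1);
      }
      bp = sub;
    }
    double thr = (n_keep > 0 && (int)kept.size() >= n_keep)
      ? kept[n_keep - 1] : INF;
    NumericVector gr = NumericVector::create(grs(c, 0), grs(c, 1));
    NumericVector r = alpha_search_pruned(D, gt, bp, gr, thr);
    out(c, 0) = r[0];
    out(c, 1) = r[1];
    if (n_keep > 0 && r[0] < thr) {
      kept.insert(std::lower_bound(kept.begin(), kept.end(), r[0]), r[0]);
      if ((int)kept.size() > n_keep) kept.pop_back();
    }
  }
  return out;
}
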