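#include <Rcpp.h>
#include <vector>
#include <queue>
#include <limits>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Exact Euclidean distance transform (Felzenszwalb & Huttenlocher squared-
// distance lower-envelope algorithm, applied per column then per row).
// ---------------------------------------------------------------------------

static void dt1d(std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
               (2.0 * q - 2.0 * v[k]);
    while (s <= z[k]) {
      --k;
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    d[q] = (q - v[k]) * (double)(q - v[k]) + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericMatrix edt_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  // large finite sentinel: infinity breaks the envelope intersections
  // (INF - INF) on all-foreground columns
  const double INF = 1e12;
  NumericMatrix g(H, W);
  // squared distances down columns
  {
    std::vector<double> f(H), d(H);
    for (int j = 0; j < W; ++j) {
      for (int i = 0; i < H; ++i) f[i] = mask(i, j) ? INF : 0.0;
      dt1d(f, d, H);
      for (int i = 0; i < H; ++i) g(i, j) = d[i];
    }
  }
  // then across rows
  {
    std::vector<double> f(W), d(W);
    for (int i = 0; i < H; ++i) {
      for (int j = 0; j < W; ++j) f[j] = g(i, j);
      dt1d(f, d, W);
      for (int j = 0; j < W; ++j) g(i, j) = std::sqrt(d[j]);
    }
  }
  return g;
}

// ---------------------------------------------------------------------------
// Polyline rasterization: mark pixels whose center lies strictly closer than
// diameter/2 to any sample point of the (densely sampled) centerline.
// pts: m x 2 matrix of (row, col), 0-based, possibly fractional.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix rasterize_points_cpp(NumericMatrix pts, double diameter,
                                   int n, int p) {
  IntegerMatrix out(n, p);
  if (pts.nrow() == 0 || diameter < 1.0) return out;
  // the -0.2 px calibration keeps the rendered thickness (as measured by
  // the max distance transform of the band) within half a pixel of
  // diameter/2 at every orientation of the pixel grid
  const double r = std::max(0.5, diameter / 2.0 - 0.2);
  const double r2 = r * r;
  NumericMatrix d2(n, p);
  std::fill(d2.begin(), d2.end(), std::numeric_limits<double>::infinity());
  const int w = (int)std::ceil(r) + 1;
  for (int q = 0; q < pts.nrow(); ++q) {
    const double y = pts(q, 0), x = pts(q, 1);
    const int i0 = std::max(0, (int)std::floor(y) - w);
    const int i1 = std::min(n - 1, (int)std::ceil(y) + w);
    const int j0 = std::max(0, (int)std::floor(x) - w);
    const int j1 = std::min(p - 1, (int)std::ceil(x) + w);
    for (int j = j0; j <= j1; ++j)
      for (int i = i0; i <= i1; ++i) {
        const double dd = (i - y) * (i - y) + (j - x) * (j - x);
        if (dd < d2(i, j)) d2(i, j) = dd;
      }
  }
  for (int j = 0; j < p; ++j)
    for (int i = 0; i < n; ++i)
      if (d2(i, j) < r2) out(i, j) = 1;
  return out;
}

// ---------------------------------------------------------------------------
// 8-connected component labeling (BFS).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix label_components_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int j0 = 0; j0 < W; ++j0)
    for (int i0 = 0; i0 < H; ++i0) {
      if (!mask(i0, j0) || lab(i0, j0)) continue;
      lab(i0, j0) = ++next;
      q.push(std::make_pair(i0, j0));
      while (!q.empty()) {
        const int i = q.front().first, j = q.front().second;
        q.pop();
        for (int dj = -1; dj <= 1; ++dj)
          for (int di = -1; di <= 1; ++di) {
            const int ii = i + di, jj = j + dj;
            if (ii < 0 || ii >= H || jj < 0 || jj >= W) continue;
            if (mask(ii, jj) && !lab(ii, jj)) {
              lab(ii, jj) = next;
              q.push(std::make_pair(ii, jj));
            }
          }
      }
    }
  return lab;
}

// ---------------------------------------------------------------------------
// Zhang-Suen thinning to a 1-px skeleton.
// ---------------------------------------------------------------------------

static inline int at(const IntegerMatrix& m, int i, int j) {
  if (i < 0 || i >= m.nrow() || j < 0 || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// [[Rcpp::export]]
IntegerMatrix thin_cpp(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix img(clone(mask));
  bool changed = true;
  while (changed) {
    changed = false;
    for (int step = 0; step < 2; ++step) {
      std::vector<std::pair<int, int> > del;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          if (!img(i, j)) continue;
          // neighbours P2..P9 clockwise from north
          const int p2 = at(img, i - 1, j),     p3 = at(img, i - 1, j + 1);
          const int p4 = at(img, i, j + 1),     p5 = at(img, i + 1, j + 1);
          const int p6 = at(img, i + 1, j),     p7 = at(img, i + 1, j - 1);
          const int p8 = at(img, i, j - 1),     p9 = at(img, i - 1, j - 1);
          const int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = 0;
          const int seq[9] = {p2, p3, p4, p5, p6, p7, p8, p9, p2};
          for (int t = 0; t < 8; ++t)
            if (seq[t] == 0 && seq[t + 1] == 1) ++A;
          if (A != 1) continue;
          if (step == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          del.push_back(std::make_pair(i, j));
        }
      for (size_t t = 0; t < del.size(); ++t)
        img(del[t].first, del[t].second) = 0;
      if (!del.empty()) changed = true;
    }
  }
  return img;
}
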