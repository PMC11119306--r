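// Low-level raster operations backing the segmentation stage:
// exact Euclidean distance transform, connected-component labeling,
// seeded (marker) watershed, and chain-code boundary tracing.
// Matrices are column-major (R layout); linear index i = r + c * nr.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const int DR8[8] = {0, 1, 1, 1, 0, -1, -1, -1};
static const int DC8[8] = {1, 1, 0, -1, -1, -1, 0, 1};

// ---- exact squared EDT (Felzenszwalb & Huttenlocher), 1-D transform ----
static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
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
    z[k + 1] = std::numeric_limits<double>::infinity();
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Euclidean distance (px) from each foreground pixel to the nearest
// background pixel; 0 on background.
// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  const double INF = 1e18;
  NumericMatrix g(nr, nc);
  // pass 1: columns
  std::vector<double> f(nr), d(nr);
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = mask(r, c) ? INF : 0.0;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  // pass 2: rows
  std::vector<double> f2(nc), d2(nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f2[c] = g(r, c);
    dt1d(f2, d2, nc);
    for (int c = 0; c < nc; ++c) g(r, c) = std::sqrt(d2[c]);
  }
  return g;
}

// 8-connected components of a binary mask; labels 1..k in raster
// (column-major) order of first encounter, background 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label_components(const LogicalMatrix& mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int i = stack.back();
        stack.pop_back();
        int rr = i % nr, cc = i / nr;
        for (int k = 0; k < 8; ++k) {
          int r2 = rr + DR8[k], c2 = cc + DC8[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) && !lab(r2, c2)) {
            lab(r2, c2) = next;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  return lab;
}

struct QItem {
  double priority;  // EDT value: flood high ground first
  long order;       // FIFO tie-break for determinism
  int idx;
};
struct QCmp {
  bool operator()(const QItem& a, const QItem& b) const {
    if (a.priority != b.priority) return a.priority < b.priority;
    return a.order > b.order;
  }
};

// Marker-based watershed by descending-distance region growing within the
// foreground mask. seeds: 0 = unlabeled, >0 = marker label.
// [[Rcpp::export]]
IntegerMatrix cpp_watershed(const NumericMatrix& dist, const IntegerMatrix& seeds,
                            const LogicalMatrix& mask) {
  int nr = dist.nrow(), nc = dist.ncol();
  IntegerMatrix lab(nr, nc);
  std::priority_queue<QItem, std::vector<QItem>, QCmp> q;
  long order = 0;
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      if (seeds(r, c) > 0) {
        lab(r, c) = seeds(r, c);
        q.push({dist(r, c), order++, r + c * nr});
      }
  while (!q.empty()) {
    QItem it = q.top();
    q.pop();
    int r = it.idx % nr, c = it.idx / nr;
    for (int k = 0; k < 8; ++k) {
      int r2 = r + DR8[k], c2 = c + DC8[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      if (!mask(r2, c2) || lab(r2, c2)) continue;
      lab(r2, c2) = lab(r, c);
      q.push({dist(r2, c2), order++, r2 + c2 * nr});
    }
  }
  return lab;
}

// Chain-code (Moore neighbor tracing) outer-boundary perimeter per label.
// Step weights: axial moves count w_axial, diagonal moves w_diag.
// Labels of area 1 get the unit-square convention perimeter 4.
// [[Rcpp::export]]
NumericVector cpp_perimeters(const IntegerMatrix& lab, int nlab,
                             double w_axial, double w_diag) {
  int nr = lab.nrow(), nc = lab.ncol();
  NumericVector per(nlab);
  std::vector<int> start(nlab, -1), area(nlab, 0);
  // raster scan rows-first so the start pixel has background to the West
  for (int r = 0; r < nr; ++r)
    for (int c = 0; c < nc; ++c) {
      int L = lab(r, c);
      if (L > 0) {
        if (start[L - 1] < 0) start[L - 1] = r + c * nr;
        ++area[L - 1];
      }
    }
  for (int L = 1; L <= nlab; ++L) {
    if (start[L - 1] < 0) {
      per[L - 1] = NA_REAL;
      continue;
    }
    if (area[L - 1] == 1) {
      per[L - 1] = 4.0;
      continue;
    }
    int sr = start[L - 1] % nr, sc = start[L - 1] / nr;
    double p = 0.0;
    // Moore tracing, clockwise; entry direction starts at West (index 4)
    int r = sr, c = sc;
    int back = 4;  // direction from current pixel toward the backtrack pixel
    int firstDir = -1, steps = 0, maxSteps = 8 * (nr * nc);
    while (steps < maxSteps) {
      int d = -1;
      // sweep clockwise from the backtrack neighbor
      for (int k = 1; k <= 8; ++k) {
        int cand = (back + k) % 8;
        int r2 = r + DR8[cand], c2 = c + DC8[cand];
        if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
        if (lab(r2, c2) == L) {
          d = cand;
          break;
        }
      }
      if (d < 0) break;  // isolated pixel (handled above) — safety
      if (firstDir < 0) firstDir = d;
      else if (r == sr && c == sc && d == firstDir) break;  // Jacob's stop
      p += (d % 2 == 0) ? w_axial : w_diag;
      // move; new backtrack points to the pixel we came from
      r += DR8[d];
      c += DC8[d];
      back = (d + 4) % 8;  // reverse of the travel direction
      ++steps;
    }
    per[L - 1] = p;
  }
  return per;
}
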