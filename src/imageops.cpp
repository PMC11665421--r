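#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Connected-component labeling of a logical matrix by iterative flood fill.
// connectivity is 4 or 8; labels are 1..k in scan order, 0 = background.
// [[Rcpp::export]]
IntegerMatrix cpp_label(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int* dr = (connectivity == 8) ? dr8 : dr4;
  const int* dc = (connectivity == 8) ? dc8 : dc4;
  const int nd = (connectivity == 8) ? 8 : 4;
  int next = 0;
  std::vector<int> stack;
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (!mask(r, c) || lab(r, c) != 0) continue;
      ++next;
      lab(r, c) = next;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc = idx / nr;
        for (int d = 0; d < nd; ++d) {
          int rr = cr + dr[d], cch = cc + dc[d];
          if (rr < 0 || rr >= nr || cch < 0 || cch >= nc) continue;
          if (mask(rr, cch) && lab(rr, cch) == 0) {
            lab(rr, cch) = next;
            stack.push_back(rr + cch * nr);
          }
        }
      }
    }
  }
  return lab;
}

static void dt1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  // Felzenszwalb & Huttenlocher lower-envelope 1D squared distance transform.
  // Parabolas with infinite height never contribute and are skipped.
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = -1;
  for (int q = 0; q < n; ++q) {
    if (f[q] == INF) continue;
    if (k < 0) {
      k = 0;
      v[0] = q;
      z[0] = -INF;
      z[1] = INF;
      continue;
    }
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
    z[k + 1] = INF;
  }
  if (k < 0) {
    for (int q = 0; q < n; ++q) d[q] = INF;
    return;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = (double)q - v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// Exact Euclidean distance (in pixels) from every pixel to the nearest
// TRUE pixel of `sites`. Pixels inside `sites` get distance 0. If there is
// no TRUE pixel anywhere, all distances are Inf.
// [[Rcpp::export]]
NumericMatrix cpp_edt(const LogicalMatrix& sites) {
  const int nr = sites.nrow(), nc = sites.ncol();
  const double INF = std::numeric_limits<double>::infinity();
  NumericMatrix d2(nr, nc);
  // column pass
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = sites(r, c) ? 0.0 : INF;
    dt1d(f, d, nr);
    for (int r = 0; r < nr; ++r) d2(r, c) = d[r];
  }
  // row pass
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = d2(r, c);
    dt1d(f, d, nc);
    for (int c = 0; c < nc; ++c) d2(r, c) = d[c];
  }
  NumericMatrix out(nr, nc);
  for (int i = 0; i < nr * nc; ++i)
    out[i] = (d2[i] == INF) ? INF : std::sqrt(d2[i]);
  return out;
}
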