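#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Binary image morphology kernels shared by tissue_detection and
// signal_quantification. Masks come in as LogicalMatrix (column-major),
// NA is not allowed and treated as background.

// [[Rcpp::export(name = ".cc_label_cpp")]]
IntegerMatrix cc_label_cpp(const LogicalMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix labels(nr, nc);
  std::vector<int> stack;
  stack.reserve(1024);
  int next_label = 0;

  // neighbour offsets (dr, dc)
  static const int dr8[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  static const int dc8[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;
  const int nn = (connectivity == 4) ? 4 : 8;

  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) {
      if (mask(r, c) != TRUE || labels(r, c) != 0) continue;
      ++next_label;
      labels(r, c) = next_label;
      stack.push_back(r + c * nr);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cr = idx % nr, cc2 = idx / nr;
        for (int k = 0; k < nn; ++k) {
          int r2 = cr + dr[k], c2 = cc2 + dc[k];
          if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
          if (mask(r2, c2) == TRUE && labels(r2, c2) == 0) {
            labels(r2, c2) = next_label;
            stack.push_back(r2 + c2 * nr);
          }
        }
      }
    }
  }
  labels.attr("n_components") = next_label;
  return labels;
}

// Fill holes: background components not reachable from the image border
// (4-connectivity on the complement) become foreground.
// [[Rcpp::export(name = ".fill_holes_cpp")]]
LogicalMatrix fill_holes_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  std::vector<char> outside(static_cast<size_t>(nr) * nc, 0);
  std::vector<int> stack;
  stack.reserve(1024);

  auto push_if_bg = [&](int r, int c) {
    size_t idx = static_cast<size_t>(r) + static_cast<size_t>(c) * nr;
    if (mask(r, c) != TRUE && !outside[idx]) {
      outside[idx] = 1;
      stack.push_back(static_cast<int>(idx));
    }
  };
  for (int r = 0; r < nr; ++r) { push_if_bg(r, 0); push_if_bg(r, nc - 1); }
  for (int c = 0; c < nc; ++c) { push_if_bg(0, c); push_if_bg(nr - 1, c); }

  static const int dr4[4] = {-1, 0, 0, 1};
  static const int dc4[4] = {0, -1, 1, 0};
  while (!stack.empty()) {
    int idx = stack.back();
    stack.pop_back();
    int cr = idx % nr, cc2 = idx / nr;
    for (int k = 0; k < 4; ++k) {
      int r2 = cr + dr4[k], c2 = cc2 + dc4[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      push_if_bg(r2, c2);
    }
  }

  LogicalMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = (mask(r, c) == TRUE) ||
                  !outside[static_cast<size_t>(r) + static_cast<size_t>(c) * nr];
  return out;
}

// Squared Euclidean distance from every pixel to the nearest background
// (FALSE) pixel, by the exact two-pass lower-envelope algorithm. Background
// pixels get 0. A large finite sentinel (exceeding any achievable squared
// distance) stands in for "no background in reach" so the lower envelope
// stays well defined on all-foreground lines.
static void edt_1d(const std::vector<double>& f, std::vector<double>& d, int n) {
  std::vector<int> v(n);
  std::vector<double> z(n + 1);
  int k = 0;
  v[0] = 0;
  z[0] = -std::numeric_limits<double>::infinity();
  z[1] = std::numeric_limits<double>::infinity();
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      int p = v[k];
      s = ((f[q] + q * (double)q) - (f[p] + p * (double)p)) / (2.0 * q - 2.0 * p);
      if (s <= z[k]) { --k; } else break;
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

// [[Rcpp::export(name = ".edt_sq_cpp")]]
NumericMatrix edt_sq_cpp(const LogicalMatrix& mask) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const double BIG =
      1.0 + (double)nr * nr + (double)nc * nc;  // > any true squared distance
  NumericMatrix g(nr, nc);

  // pass 1: columns
  std::vector<double> f(std::max(nr, nc)), d(std::max(nr, nc));
  for (int c = 0; c < nc; ++c) {
    for (int r = 0; r < nr; ++r) f[r] = (mask(r, c) == TRUE) ? BIG : 0.0;
    edt_1d(f, d, nr);
    for (int r = 0; r < nr; ++r) g(r, c) = d[r];
  }
  // pass 2: rows
  NumericMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) f[c] = g(r, c);
    edt_1d(f, d, nc);
    for (int c = 0; c < nc; ++c) out(r, c) = d[c];
  }
  return out;
}
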