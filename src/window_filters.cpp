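#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Reflect an out-of-range index back into [0, n) with the border pixel
// repeated (scipy.ndimage "reflect" convention: d c b a | a b c d | d c b a).
static inline int reflect_idx(int i, int n) {
  if (n == 1) return 0;
  while (i < 0 || i >= n) {
    if (i < 0) i = -i - 1;
    if (i >= n) i = 2 * n - i - 1;
  }
  return i;
}

// Max over a centred w x w window, reflect-padded borders.
// [[Rcpp::export]]
NumericMatrix cpp_local_max(const NumericMatrix& x, int w) {
  const int nr = x.nrow(), nc = x.ncol(), r = w / 2;
  NumericMatrix out(nr, nc);
  // separable: row-direction pass, then column-direction pass
  NumericMatrix tmp(nr, nc);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int di = -r; di <= r; ++di) {
        double v = x(reflect_idx(i + di, nr), j);
        if (v > m) m = v;
      }
      tmp(i, j) = m;
    }
  }
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      double m = R_NegInf;
      for (int dj = -r; dj <= r; ++dj) {
        double v = tmp(i, reflect_idx(j + dj, nc));
        if (v > m) m = v;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// Fraction of pixels in the centred w x w window whose value is <= the
// centre pixel's value (ties count in), reflect-padded.
// [[Rcpp::export]]
NumericMatrix cpp_rank_fraction(const NumericMatrix& x, int w) {
  const int nr = x.nrow(), nc = x.ncol(), r = w / 2;
  const double total = (double)w * (double)w;
  NumericMatrix out(nr, nc);
  std::vector<int> ri(w), rj(w);
  for (int j = 0; j < nc; ++j) {
    for (int dj = -r; dj <= r; ++dj) rj[dj + r] = reflect_idx(j + dj, nc);
    for (int i = 0; i < nr; ++i) {
      for (int di = -r; di <= r; ++di) ri[di + r] = reflect_idx(i + di, nr);
      const double c = x(i, j);
      int cnt = 0;
      for (int b = 0; b < w; ++b)
        for (int a = 0; a < w; ++a)
          if (x(ri[a], rj[b]) <= c) ++cnt;
      out(i, j) = cnt / total;
    }
  }
  return out;
}

// Mean of the k = ceil(frac * w * w) largest values in the centred w x w
// window, reflect-padded.
// [[Rcpp::export]]
NumericMatrix cpp_topfrac_mean(const NumericMatrix& x, int w, double frac) {
  const int nr = x.nrow(), nc = x.ncol(), r = w / 2;
  const int n = w * w;
  int k = (int)std::ceil(frac * n);
  if (k < 1) k = 1;
  if (k > n) k = n;
  NumericMatrix out(nr, nc);
  std::vector<int> ri(w), rj(w);
  std::vector<double> buf(n);
  for (int j = 0; j < nc; ++j) {
    for (int dj = -r; dj <= r; ++dj) rj[dj + r] = reflect_idx(j + dj, nc);
    for (int i = 0; i < nr; ++i) {
      for (int di = -r; di <= r; ++di) ri[di + r] = reflect_idx(i + di, nr);
      int p = 0;
      for (int b = 0; b < w; ++b)
        for (int a = 0; a < w; ++a)
          buf[p++] = x(ri[a], rj[b]);
      std::nth_element(buf.begin(), buf.begin() + (k - 1), buf.end(),
                       std::greater<double>());
      double s = 0.0;
      for (int q = 0; q < k; ++q) s += buf[q];
      out(i, j) = s / k;
    }
  }
  return out;
}
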