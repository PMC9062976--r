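#include <Rcpp.h>
using namespace Rcpp;

// Dynamic time warping with absolute-difference local cost and the
// symmetric step set {(1,0),(0,1),(1,1)}.  Optionally restricted to a
// Sakoe-Chiba band of half-width `window` (< 0 disables the band) and
// optionally normalised by the length (number of cells) of the optimal
// warping path.  Ties between predecessors are broken deterministically:
// diagonal first, then the vertical step, then the horizontal step.
static double dtw_core(const NumericVector& a, const NumericVector& b,
                       int window, bool normalize) {
  const int n = a.size(), m = b.size();
  const double INF = std::numeric_limits<double>::infinity();
  // cumulative cost and path length (cells on the optimal path so far)
  std::vector<double> cost((n + 1) * (m + 1), INF);
  std::vector<int> plen((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };
  cost[at(0, 0)] = 0.0;

  for (int i = 1; i <= n; ++i) {
    int jlo = 1, jhi = m;
    if (window >= 0) {
      // band defined on indices mapped to a common scale
      double center = (double)i * m / n;
      jlo = std::max(1, (int)std::ceil(center - window));
      jhi = std::min(m, (int)std::floor(center + window));
    }
    for (int j = jlo; j <= jhi; ++j) {
      double d = std::fabs(a[i - 1] - b[j - 1]);
      double cd = cost[at(i - 1, j - 1)];
      double cv = cost[at(i - 1, j)];
      double ch = cost[at(i, j - 1)];
      double best = cd; int from = 0;
      if (cv < best) { best = cv; from = 1; }
      if (ch < best) { best = ch; from = 2; }
      if (best == INF) continue;
      cost[at(i, j)] = best + d;
      int p = (from == 0) ? plen[at(i - 1, j - 1)]
            : (from == 1) ? plen[at(i - 1, j)]
                          : plen[at(i, j - 1)];
      plen[at(i, j)] = p + 1;
    }
  }
  double res = cost[at(n, m)];
  if (!std::isfinite(res))
    stop("DTW window too narrow: no admissible warping path");
  if (normalize) res /= (double)plen[at(n, m)];
  return res;
}

// [[Rcpp::export]]
double cpp_dtw(NumericVector a, NumericVector b, int window, bool normalize) {
  if (a.size() == 0 || b.size() == 0) stop("empty series");
  return dtw_core(a, b, window, normalize);
}

// [[Rcpp::export]]
NumericMatrix cpp_dtw_matrix(List series, int window, bool normalize) {
  const int n = series.size();
  NumericMatrix D(n, n);
  std::vector<NumericVector> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<NumericVector>(series[i]);
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      double d = dtw_core(s[i], s[j], window, normalize);
      D(i, j) = d;
      D(j, i) = d;
    }
  }
  return D;
}

// [[Rcpp::export]]
NumericVector cpp_dtw_one_to_many(NumericVector x, List series, int window,
                                  bool normalize) {
  const int n = series.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = dtw_core(x, as<NumericVector>(series[i]), window, normalize);
  return out;
}
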