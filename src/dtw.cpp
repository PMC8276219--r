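// Dynamic time warping with squared pointwise cost, step set
// {(1,0),(0,1),(1,1)} and an optional Sakoe-Chiba band of half-width
// ceil(band_fraction * max(n, m)) around the main diagonal.

#include <Rcpp.h>
#include <cmath>
#include <limits>
using namespace Rcpp;

static double dtw_core(const double* a, int n, const double* b, int m,
                       double band_fraction) {
  const double INF = std::numeric_limits<double>::infinity();
  int w;
  if (band_fraction >= 1.0) {
    w = std::max(n, m);
  } else {
    w = (int)std::ceil(band_fraction * (double)std::max(n, m));
  }
  if (std::abs(n - m) > w)
    return -1.0; // infeasible band, caller raises the named error

  std::vector<double> prev(m + 1, INF), cur(m + 1, INF);
  prev[0] = 0.0;
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(1, i - w), jhi = std::min(m, i + w);
    std::fill(cur.begin(), cur.end(), INF);
    for (int j = jlo; j <= jhi; ++j) {
      double d = a[i - 1] - b[j - 1];
      double best = prev[j - 1];            // (1,1)
      if (prev[j] < best) best = prev[j];   // (1,0)
      if (cur[j - 1] < best) best = cur[j - 1]; // (0,1)
      cur[j] = d * d + best;
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export(name = ".dtw_dist_cpp")]]
double dtw_dist_cpp(NumericVector a, NumericVector b, double band_fraction) {
  if (a.size() == 0 || b.size() == 0)
    stop("empty_sequence: dtw needs non-empty inputs");
  double d = dtw_core(a.begin(), a.size(), b.begin(), b.size(), band_fraction);
  if (d < 0) stop("band_too_narrow: no warping path fits the Sakoe-Chiba band");
  return d;
}

// distances from one query to every row of a training matrix
// [[Rcpp::export(name = ".dtw_dists_cpp")]]
NumericVector dtw_dists_cpp(NumericMatrix train, NumericVector query,
                            double band_fraction) {
  int n = train.nrow(), m = train.ncol();
  if (n == 0 || m == 0 || query.size() == 0)
    stop("empty_sequence: dtw needs non-empty inputs");
  NumericVector out(n);
  std::vector<double> row(m);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < m; ++j) row[j] = train(i, j);
    double d = dtw_core(row.data(), m, query.begin(), query.size(),
                        band_fraction);
    if (d < 0)
      stop("band_too_narrow: no warping path fits the Sakoe-Chiba band");
    out[i] = d;
  }
  return out;
}
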