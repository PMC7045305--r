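#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

// k-NN statistic per point: distance to the k-th nearest neighbor
// (method = 0) or the mean of the k nearest distances (method = 1).
static double knn_stat_point(std::vector<double>& d2, int k, int method) {
  std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
  if (method == 0) return std::sqrt(d2[k - 1]);
  double acc = 0.0;
  for (int j = 0; j < k; ++j) acc += std::sqrt(d2[j]);
  return acc / k;
}

// [[Rcpp::export]]
double mean_knn_distance_cpp(NumericMatrix pts, int k, int method = 0) {
  const int n = pts.nrow();
  if (n <= k) stop("need more than k points");
  std::vector<double> d2(n - 1);
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    const double xi = pts(i, 0), yi = pts(i, 1);
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xi - pts(j, 0), dy = yi - pts(j, 1);
      d2[m++] = dx * dx + dy * dy;
    }
    total += knn_stat_point(d2, k, method);
  }
  return total / n;
}

// Null distribution of the mean k-NN statistic for n uniform points in a
// rectangle; uses R's RNG so results follow set.seed().
// [[Rcpp::export]]
NumericVector knn_null_cpp(int n, int k, int n_shuffles, NumericVector bounds,
                           int method = 0) {
  NumericVector out(n_shuffles);
  NumericMatrix pts(n, 2);
  for (int s = 0; s < n_shuffles; ++s) {
    NumericVector xs = runif(n, bounds[0], bounds[1]);
    NumericVector ys = runif(n, bounds[2], bounds[3]);
    for (int i = 0; i < n; ++i) { pts(i, 0) = xs[i]; pts(i, 1) = ys[i]; }
    out[s] = mean_knn_distance_cpp(pts, k, method);
  }
  return out;
}
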