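#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Distance from each query point to its k-th nearest point of x (1-d).
// exclude_zero drops exact-zero distances (query coincides with a sample).
// [[Rcpp::export]]
NumericVector kth_dist_1d(NumericVector q, NumericVector x, int k,
                          bool exclude_zero) {
  int m = q.size(), n = x.size();
  if (k < 1 || k > n) stop("need 1 <= k <= number of samples");
  NumericVector out(m);
  std::vector<double> d;
  d.reserve(n);
  for (int i = 0; i < m; ++i) {
    d.clear();
    for (int j = 0; j < n; ++j) {
      double dd = std::fabs(q[i] - x[j]);
      if (exclude_zero && dd == 0.0) continue;
      d.push_back(dd);
    }
    if ((int)d.size() < k) stop("fewer than k usable neighbors");
    std::nth_element(d.begin(), d.begin() + (k - 1), d.end());
    out[i] = d[k - 1];
  }
  return out;
}

// k-th nearest-neighbor Euclidean distance within a point cloud (self
// excluded), for the Kozachenko-Leonenko entropy estimator.
// [[Rcpp::export]]
NumericVector kth_nn_dist(NumericMatrix X, int k) {
  int n = X.nrow(), d = X.ncol();
  if (k < 1 || k >= n) stop("need 1 <= k < n");
  NumericVector out(n);
  std::vector<double> dist(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        double diff = X(i, c) - X(j, c);
        s += diff * diff;
      }
      dist[m++] = s;
    }
    std::nth_element(dist.begin(), dist.begin() + (k - 1), dist.end());
    out[i] = std::sqrt(dist[k - 1]);
  }
  return out;
}

// Mean future value over the k nearest training points by |tau - tau'|.
// Ties are broken by smaller tau then by training index so predictions are
// deterministic.  If fewer than k points exist, all are used.
// [[Rcpp::export]]
NumericVector knn1d_mean(NumericVector train_tau, NumericVector train_y,
                         NumericVector query_tau, int k) {
  int n = train_tau.size(), m = query_tau.size();
  if (n == 0) stop("empty training set");
  if (k < 1) stop("k must be >= 1");
  int kk = std::min(k, n);
  NumericVector out(m);
  typedef std::pair<double, std::pair<double, int> > rec; // (dist, (tau, idx))
  std::vector<rec> d(n);
  for (int i = 0; i < m; ++i) {
    for (int j = 0; j < n; ++j)
      d[j] = rec(std::fabs(query_tau[i] - train_tau[j]),
                 std::make_pair(train_tau[j], j));
    std::nth_element(d.begin(), d.begin() + (kk - 1), d.end());
    // nth_element with default pair comparison already orders ties
    double s = 0.0;
    for (int j = 0; j < kk; ++j) s += train_y[d[j].second.second];
    out[i] = s / kk;
  }
  return out;
}
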