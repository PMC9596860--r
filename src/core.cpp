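#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Mean over all points of the Euclidean distance to each point's k-th
// nearest other point. Brute force O(n^2); n is at most a few tens of
// thousands per cell, so this stays well under a second.
// [[Rcpp::export(name = ".knn_kth_mean")]]
double knn_kth_mean(NumericMatrix coords, int k) {
  const int n = coords.nrow();
  if (k < 1) stop("k must be >= 1");
  if (n < k + 1) stop("need at least k+1 points");
  std::vector<double> x(n), y(n), z(n), d2(n - 1);
  for (int i = 0; i < n; ++i) {
    x[i] = coords(i, 0); y[i] = coords(i, 1); z[i] = coords(i, 2);
  }
  double total = 0.0;
  for (int i = 0; i < n; ++i) {
    int m = 0;
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = x[i] - x[j], dy = y[i] - y[j], dz = z[i] - z[j];
      d2[m++] = dx * dx + dy * dy + dz * dz;
    }
    std::nth_element(d2.begin(), d2.begin() + (k - 1), d2.end());
    total += std::sqrt(d2[k - 1]);
  }
  return total / n;
}

// For each query point, the mean of the k smallest Euclidean distances to
// the reference set. Queries and references are cube-center coordinates.
// [[Rcpp::export(name = ".topk_mean_dist")]]
NumericVector topk_mean_dist(NumericMatrix query, NumericMatrix ref, int k) {
  const int nq = query.nrow(), nr = ref.nrow();
  if (k < 1) stop("k must be >= 1");
  if (nr < k) stop("reference set smaller than k");
  std::vector<double> rx(nr), ry(nr), rz(nr);
  for (int j = 0; j < nr; ++j) {
    rx[j] = ref(j, 0); ry[j] = ref(j, 1); rz[j] = ref(j, 2);
  }
  NumericVector out(nq);
  std::vector<double> best(k);
  for (int i = 0; i < nq; ++i) {
    const double qx = query(i, 0), qy = query(i, 1), qz = query(i, 2);
    int filled = 0;
    double worst = R_PosInf;  // current k-th smallest
    for (int j = 0; j < nr; ++j) {
      double dx = qx - rx[j], dy = qy - ry[j], dz = qz - rz[j];
      double d2 = dx * dx + dy * dy + dz * dz;
      if (filled < k) {
        best[filled++] = d2;
        if (filled == k) {
          std::make_heap(best.begin(), best.end());
          worst = best.front();
        }
      } else if (d2 < worst) {
        std::pop_heap(best.begin(), best.end());
        best[k - 1] = d2;
        std::push_heap(best.begin(), best.end());
        worst = best.front();
      }
    }
    double s = 0.0;
    for (int m = 0; m < k; ++m) s += std::sqrt(best[m]);
    out[i] = s / k;
  }
  return out;
}
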