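#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Exact k-nearest-neighbor indices within one core.
// Ties at equal squared distance are broken by ascending index, so callers
// obtain a deterministic neighbor set by passing cells pre-sorted by cell_id.
// Returns a n x k matrix of 1-based neighbor indices (self excluded).
// [[Rcpp::export(name = ".knn_indices_cpp")]]
IntegerMatrix knn_indices_cpp(NumericVector x, NumericVector y, int k) {
  const int n = x.size();
  if (k < 1) stop("k must be >= 1");
  if (n < k + 1) stop("need at least k+1 cells");
  IntegerMatrix out(n, k);
  std::vector<std::pair<double, int> > cand(n - 1);
  for (int i = 0; i < n; ++i) {
    int m = 0;
    const double xi = x[i], yi = y[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - xi, dy = y[j] - yi;
      cand[m++] = std::make_pair(dx * dx + dy * dy, j);
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int r = 0; r < k; ++r) out(i, r) = cand[r].second + 1;
  }
  return out;
}
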