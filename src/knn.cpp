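#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Exact k-nearest-neighbor search by linear scan with an insertion list.
// Ties in distance are broken by the smaller reference index (strict '<'
// comparison keeps the earlier candidate), so results are deterministic.
// query, ref: points in rows. If exclude_self is true the two sets are the
// same and ref index == query index is skipped.
// [[Rcpp::export(name = ".cpp_knn")]]
List cpp_knn(NumericMatrix query, NumericMatrix ref, int k, bool exclude_self) {
  const int n = query.nrow(), m = ref.nrow(), d = query.ncol();
  if (ref.ncol() != d) stop("dimension mismatch");
  const int avail = m - (exclude_self ? 1 : 0);
  if (k < 1 || k > avail) stop("k out of range");

  NumericMatrix dist(n, k);
  IntegerMatrix index(n, k);
  std::vector<double> bd(k);
  std::vector<int> bi(k);

  for (int i = 0; i < n; ++i) {
    int filled = 0;
    for (int j = 0; j < m; ++j) {
      if (exclude_self && j == i) continue;
      double s = 0.0;
      for (int c = 0; c < d; ++c) {
        const double diff = query(i, c) - ref(j, c);
        s += diff * diff;
      }
      if (filled == k && s >= bd[k - 1]) continue;
      // insertion position: strictly greater distances shift right, so among
      // equal distances the earlier (smaller) index stays first
      int pos = filled < k ? filled : k - 1;
      while (pos > 0 && bd[pos - 1] > s) {
        if (pos < k) { bd[pos] = bd[pos - 1]; bi[pos] = bi[pos - 1]; }
        --pos;
      }
      bd[pos] = s;
      bi[pos] = j;
      if (filled < k) ++filled;
    }
    for (int q = 0; q < k; ++q) {
      dist(i, q) = std::sqrt(bd[q]);
      index(i, q) = bi[q] + 1;
    }
  }
  return List::create(_["dist"] = dist, _["index"] = index);
}
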