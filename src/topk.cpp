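#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// For each column v of a symmetric correlation matrix, the k row indices
// (1-based) with the highest value, excluding the diagonal entry and any
// NA rows. Ties at the cutoff are broken in favour of the lower index:
// candidates are ordered by (value descending, index ascending).
// [[Rcpp::export(name = ".topk_columns")]]
IntegerMatrix topk_columns(NumericMatrix C, int k) {
  const int n = C.nrow();
  if (k < 1) stop("k must be >= 1");
  IntegerMatrix out(k, n);
  std::vector<std::pair<double, int> > cand;
  cand.reserve(n);
  for (int v = 0; v < n; ++v) {
    cand.clear();
    for (int u = 0; u < n; ++u) {
      if (u == v) continue;
      double val = C(u, v);
      if (NumericVector::is_na(val)) continue;
      cand.push_back(std::make_pair(-val, u));
    }
    if ((int)cand.size() < k) {
      // fewer valid neighbours than k (or an all-NA column): pad with NA
      std::sort(cand.begin(), cand.end());
      for (int i = 0; i < k; ++i)
        out(i, v) = i < (int)cand.size() ? cand[i].second + 1 : NA_INTEGER;
      continue;
    }
    std::partial_sort(cand.begin(), cand.begin() + k, cand.end());
    for (int i = 0; i < k; ++i) out(i, v) = cand[i].second + 1;
  }
  return out;
}
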