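#include <Rcpp.h>
using namespace Rcpp;

// Score-maximal monotone chain of anchors under a gap constraint.
// Anchors must be sorted by a (ascending), ties by b. A chain takes strictly
// increasing a and b with consecutive steps satisfying
// max(da, db) <= maxstep (maxstep = gap_limit + 1, gap measured in genes).
// Ties in score break toward more anchors, then smaller start a.
// Returns 1-based indices of the best chain, in order.
// [[Rcpp::export]]
IntegerVector chain_best_cpp(IntegerVector a, IntegerVector b, NumericVector s,
                             int maxstep) {
  int n = a.size();
  if (n == 0) return IntegerVector(0);
  std::vector<double> dp(n);
  std::vector<int> len(n), pred(n, -1), starta(n);
  int lo = 0;
  for (int j = 0; j < n; ++j) {
    dp[j] = s[j]; len[j] = 1; starta[j] = a[j];
    while (lo < j && a[lo] < a[j] - maxstep) ++lo;
    for (int i = lo; i < j; ++i) {
      int da = a[j] - a[i];
      if (da < 1 || da > maxstep) continue;
      int db = b[j] - b[i];
      if (db < 1 || db > maxstep) continue;
      double cand = dp[i] + s[j];
      bool better = cand > dp[j] + 1e-9;
      if (!better && std::abs(cand - dp[j]) <= 1e-9) {
        if (len[i] + 1 > len[j]) better = true;
        else if (len[i] + 1 == len[j] && starta[i] < starta[j]) better = true;
      }
      if (better) {
        dp[j] = cand; len[j] = len[i] + 1; pred[j] = i; starta[j] = starta[i];
      }
    }
  }
  int best = 0;
  for (int j = 1; j < n; ++j) {
    bool better = dp[j] > dp[best] + 1e-9;
    if (!better && std::abs(dp[j] - dp[best]) <= 1e-9) {
      if (len[j] > len[best]) better = true;
      else if (len[j] == len[best] && starta[j] < starta[best]) better = true;
    }
    if (better) best = j;
  }
  std::vector<int> chain;
  for (int j = best; j >= 0;) {
    chain.push_back(j + 1);
    if (pred[j] < 0) break;
    j = pred[j];
  }
  std::reverse(chain.begin(), chain.end());
  return wrap(chain);
}
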