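// Nussinov maximum base-pairing DP with deterministic traceback, and the
// exact maximum nested (pseudoknot-free) subset of a given pair list.
#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

static inline bool can_pair(char x, char y) {
  return (x == 'A' && y == 'U') || (x == 'U' && y == 'A') ||
         (x == 'G' && y == 'C') || (x == 'C' && y == 'G') ||
         (x == 'G' && y == 'U') || (x == 'U' && y == 'G');
}

// Maximum-cardinality nested set of canonical pairs with j - i > min_loop.
// Traceback prefers pairing the leftmost position with its smallest
// admissible partner, so the returned structure is unique.
// [[Rcpp::export(name = ".nussinov_cpp")]]
IntegerMatrix nussinov_cpp(std::string seq, int min_loop) {
  const int L = seq.size();
  if (L == 0) return IntegerMatrix(0, 2);
  std::vector<std::vector<int> > dp(L, std::vector<int>(L, 0));
  for (int span = min_loop + 1; span < L; ++span) {
    for (int i = 0; i + span < L; ++i) {
      const int j = i + span;
      int best = dp[i + 1][j];  // i unpaired
      for (int l = i + min_loop + 1; l <= j; ++l) {
        if (!can_pair(seq[i], seq[l])) continue;
        int v = 1 + (l > i + 1 ? dp[i + 1][l - 1] : 0) +
                    (l < j ? dp[l + 1][j] : 0);
        if (v > best) best = v;
      }
      dp[i][j] = best;
    }
  }
  std::vector<std::pair<int,int> > pairs;
  std::vector<std::pair<int,int> > stack;
  stack.push_back(std::make_pair(0, L - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop || dp[i][j] == 0) continue;
    int taken = -1;
    for (int l = i + min_loop + 1; l <= j; ++l) {  // smallest partner first
      if (!can_pair(seq[i], seq[l])) continue;
      int v = 1 + (l > i + 1 ? dp[i + 1][l - 1] : 0) +
                  (l < j ? dp[l + 1][j] : 0);
      if (v == dp[i][j]) { taken = l; break; }
    }
    if (taken >= 0) {
      pairs.push_back(std::make_pair(i, taken));
      if (taken > i + 1) stack.push_back(std::make_pair(i + 1, taken - 1));
      if (taken < j) stack.push_back(std::make_pair(taken + 1, j));
    } else {
      stack.push_back(std::make_pair(i + 1, j));
    }
  }
  IntegerMatrix out(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(k, 0) = pairs[k].first + 1;   // 1-based
    out(k, 1) = pairs[k].second + 1;
  }
  return out;
}

// Exact maximum nested subset of candidate pairs (each base in at most one
// pair). `pairs` is k x 2, 1-based, i < j. Returns 1-based row indices of
// the retained pairs; ties resolved toward the lexicographically smallest
// retained pair list.
// [[Rcpp::export(name = ".max_nested_cpp")]]
IntegerVector max_nested_cpp(IntegerMatrix pairs, int L) {
  const int K = pairs.nrow();
  if (K == 0) return IntegerVector(0);
  std::vector<int> partner(L + 1, 0), rowidx(L + 1, 0);
  for (int k = 0; k < K; ++k) {
    partner[pairs(k, 0)] = pairs(k, 1);
    rowidx[pairs(k, 0)] = k + 1;
  }
  std::vector<std::vector<int> > dp(L + 2, std::vector<int>(L + 2, 0));
  for (int span = 1; span <= L; ++span) {
    for (int i = 1; i + span - 1 <= L; ++i) {
      const int j = i + span - 1;
      int best = dp[i + 1][j];
      const int l = partner[i];
      if (l > i && l <= j)
        best = std::max(best, 1 + dp[i + 1][l - 1] + dp[l + 1][j]);
      dp[i][j] = best;
    }
  }
  std::vector<int> keep;
  std::vector<std::pair<int,int> > stack;
  stack.push_back(std::make_pair(1, L));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || dp[i][j] == 0) continue;
    const int l = partner[i];
    // prefer keeping (i, l) on ties: lexicographically smallest pair list
    if (l > i && l <= j && 1 + dp[i + 1][l - 1] + dp[l + 1][j] == dp[i][j]) {
      keep.push_back(rowidx[i]);
      stack.push_back(std::make_pair(i + 1, l - 1));
      stack.push_back(std::make_pair(l + 1, j));
    } else {
      stack.push_back(std::make_pair(i + 1, j));
    }
  }
  return wrap(keep);
}
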