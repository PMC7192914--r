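#include <Rcpp.h>
using namespace Rcpp;

// Global-alignment edit cost: match 0, mismatch `mismatch`, indel `gap`.
// Distance semantics (minimised); O(nm) time, O(m) memory.
static int nw_cost(const std::string& a, const std::string& b,
                   int gap, int mismatch) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1), cur(m + 1);
  for (int j = 0; j <= m; ++j) prev[j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    cur[0] = i * gap;
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      int diag = prev[j - 1] + (ai == b[j - 1] ? 0 : mismatch);
      int up   = prev[j] + gap;
      int left = cur[j - 1] + gap;
      cur[j] = std::min(diag, std::min(up, left));
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector nw_distance_cpp(CharacterVector s1, CharacterVector s2,
                              int gap, int mismatch) {
  const int n = s1.size();
  if (s2.size() != n) stop("s1 and s2 must have equal length");
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = nw_cost(as<std::string>(s1[i]), as<std::string>(s2[i]),
                     gap, mismatch);
  }
  return out;
}

// Distances between consecutive elements of a (sorted) read vector.
// [[Rcpp::export]]
IntegerVector nw_adjacent_cpp(CharacterVector reads, int gap, int mismatch) {
  const int n = reads.size();
  if (n < 2) return IntegerVector(0);
  IntegerVector out(n - 1);
  std::string prev = as<std::string>(reads[0]);
  for (int i = 1; i < n; ++i) {
    std::string cur = as<std::string>(reads[i]);
    out[i - 1] = nw_cost(prev, cur, gap, mismatch);
    prev = std::move(cur);
  }
  return out;
}
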