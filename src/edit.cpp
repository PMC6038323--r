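#include <Rcpp.h>
#include <string>
#include <vector>
#include <algorithm>

using namespace Rcpp;

// Unit-cost Levenshtein over bytes; two-row DP. Spaces are ordinary characters.
static int lev(const std::string &a, const std::string &b) {
  const size_t n = a.size(), m = b.size();
  if (n == 0) return (int)m;
  if (m == 0) return (int)n;
  std::vector<int> prev(m + 1), cur(m + 1);
  for (size_t j = 0; j <= m; ++j) prev[j] = (int)j;
  for (size_t i = 1; i <= n; ++i) {
    cur[0] = (int)i;
    for (size_t j = 1; j <= m; ++j) {
      int sub = prev[j - 1] + (a[i - 1] == b[j - 1] ? 0 : 1);
      cur[j] = std::min(std::min(prev[j] + 1, cur[j - 1] + 1), sub);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

// [[Rcpp::export]]
IntegerVector cpp_levenshtein(CharacterVector a, CharacterVector b) {
  if (a.size() != b.size()) stop("a and b must have equal length");
  IntegerVector out(a.size());
  for (R_xlen_t i = 0; i < a.size(); ++i) {
    out[i] = lev(std::string(a[i]), std::string(b[i]));
  }
  return out;
}

// [[Rcpp::export]]
IntegerVector cpp_ed_all(std::string source, std::vector<std::string> targets) {
  IntegerVector out(targets.size());
  for (size_t j = 0; j < targets.size(); ++j) out[j] = lev(source, targets[j]);
  return out;
}

// For each source, the k nearest targets by edit distance, ties broken by
// lexicographic order of the target (lex_rank is the 1-based rank of each
// target under that order, computed once by the caller).
// [[Rcpp::export]]
List cpp_ed_topk(std::vector<std::string> sources, std::vector<std::string> targets,
                 int k, IntegerVector lex_rank) {
  const int ns = (int)sources.size(), nt = (int)targets.size();
  if (k > nt) k = nt;
  IntegerMatrix idx(k, ns);
  IntegerMatrix dst(k, ns);
  std::vector<int> ord(nt);
  std::vector<int> d(nt);
  for (int i = 0; i < ns; ++i) {
    for (int j = 0; j < nt; ++j) d[j] = lev(sources[i], targets[j]);
    for (int j = 0; j < nt; ++j) ord[j] = j;
    std::partial_sort(ord.begin(), ord.begin() + k, ord.end(),
                      [&](int x, int y) {
                        if (d[x] != d[y]) return d[x] < d[y];
                        return lex_rank[x] < lex_rank[y];
                      });
    for (int r = 0; r < k; ++r) {
      idx(r, i) = ord[r] + 1;
      dst(r, i) = d[ord[r]];
    }
    if (i % 64 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["idx"] = idx, _["dist"] = dst);
}
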