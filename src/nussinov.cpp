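#include <Rcpp.h>
#include <vector>
#include <string>
#include <utility>

using namespace Rcpp;

// Watson-Crick plus G.T (G.U) wobble, DNA alphabet
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'T') || (a == 'T' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'T') || (a == 'T' && b == 'G');
}

// Base-pair-maximizing secondary structure (Nussinov recursion) with a
// minimum hairpin loop size. Traceback is deterministic: at each
// subproblem the first admissible partner (leftmost k) achieving the
// optimum pairs with i, otherwise i stays unpaired.
// [[Rcpp::export]]
std::string nussinov_cpp(std::string s, int min_loop) {
  const int n = static_cast<int>(s.size());
  std::string db(n, '.');
  if (n == 0) return db;
  // N[i][j] stored in a flat vector, 0 <= i <= j < n
  std::vector<int> N(static_cast<size_t>(n) * n, 0);
  const int nn = n;
  auto at = [nn](int i, int j) { return static_cast<size_t>(i) * nn + j; };
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = N[at(i + 1, j)];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        if (!can_pair(s[i], s[k])) continue;
        int inner = (k - 1 >= i + 1) ? N[at(i + 1, k - 1)] : 0;
        int right = (k + 1 <= j) ? N[at(k + 1, j)] : 0;
        int cand = 1 + inner + right;
        if (cand > best) best = cand;
      }
      N[at(i, j)] = best;
    }
  }
  std::vector<std::pair<int, int>> stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || j - i <= min_loop) continue;
    if (N[at(i, j)] == 0) continue;
    bool paired = false;
    for (int k = i + min_loop + 1; k <= j; ++k) {
      if (!can_pair(s[i], s[k])) continue;
      int inner = (k - 1 >= i + 1) ? N[at(i + 1, k - 1)] : 0;
      int right = (k + 1 <= j) ? N[at(k + 1, j)] : 0;
      if (1 + inner + right == N[at(i, j)]) {
        db[i] = '(';
        db[k] = ')';
        stack.push_back(std::make_pair(i + 1, k - 1));
        stack.push_back(std::make_pair(k + 1, j));
        paired = true;
        break;
      }
    }
    if (!paired) stack.push_back(std::make_pair(i + 1, j));
  }
  return db;
}
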