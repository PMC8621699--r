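#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Watson-Crick + GU wobble pairing over {A,C,G,U}; N never pairs.
static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Base-pair maximization (Nussinov) with hairpin loops >= min_loop and an
// optional maximum pairing span. Traceback is deterministic: at (i, j) a
// pairing of i is preferred whenever it achieves the optimum, taking the
// leftmost admissible partner.
// [[Rcpp::export(name = ".nussinov_fold")]]
std::string nussinov_fold(std::string seq, int min_loop, int max_span) {
  const int n = seq.size();
  std::string db(n, '.');
  if (n == 0) return db;
  if (max_span <= 0) max_span = n;

  std::vector<std::vector<int>> M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];  // i unpaired
      int kmax = std::min(j, i + max_span - 1);
      for (int k = i + min_loop + 1; k <= kmax; ++k) {
        if (!can_pair(seq[i], seq[k])) continue;
        int inner = (k - i >= 2) ? M[i + 1][k - 1] : 0;
        int right = (k < j) ? M[k + 1][j] : 0;
        int cand = 1 + inner + right;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }

  std::vector<std::pair<int, int>> stack;
  stack.push_back({0, n - 1});
  while (!stack.empty()) {
    int i = stack.back().first, j = stack.back().second;
    stack.pop_back();
    if (i >= j || M[i][j] == 0) continue;
    bool paired = false;
    int kmax = std::min(j, i + max_span - 1);
    for (int k = i + min_loop + 1; k <= kmax; ++k) {
      if (!can_pair(seq[i], seq[k])) continue;
      int inner = (k - i >= 2) ? M[i + 1][k - 1] : 0;
      int right = (k < j) ? M[k + 1][j] : 0;
      if (1 + inner + right == M[i][j]) {
        db[i] = '(';
        db[k] = ')';
        if (k - i >= 2) stack.push_back({i + 1, k - 1});
        if (k < j) stack.push_back({k + 1, j});
        paired = true;
        break;  // leftmost partner
      }
    }
    if (!paired) stack.push_back({i + 1, j});
  }
  return db;
}
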