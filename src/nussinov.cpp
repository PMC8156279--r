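#include <Rcpp.h>
#include <vector>
#include <string>

using namespace Rcpp;

static inline bool can_pair(char a, char b) {
  return (a == 'A' && b == 'U') || (a == 'U' && b == 'A') ||
         (a == 'G' && b == 'C') || (a == 'C' && b == 'G') ||
         (a == 'G' && b == 'U') || (a == 'U' && b == 'G');
}

// Maximum base-pairing fold (Nussinov recursion) with a minimum hairpin
// loop of `min_loop` unpaired nucleotides, canonical + G:U pairs, and an
// optional mask of positions forbidden from pairing. Traceback prefers
// closing (i,j) first, then leaving i unpaired, then j, then the leftmost
// bifurcation, so the returned structure is deterministic.
// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
std::string nussinov_fold_cpp(std::string seq, LogicalVector blocked,
                              int min_loop) {
  int n = (int) seq.size();
  if ((int) blocked.size() != n) stop("blocked mask length must equal sequence length");
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int len = min_loop + 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int best = M[i + 1][j];
      if (M[i][j - 1] > best) best = M[i][j - 1];
      if (!blocked[i] && !blocked[j] && can_pair(seq[i], seq[j]) &&
          j - i - 1 >= min_loop) {
        int v = M[i + 1][j - 1] + 1;
        if (v > best) best = v;
      }
      for (int k = i + 1; k < j; ++k) {
        int v = M[i][k] + M[k + 1][j];
        if (v > best) best = v;
      }
      M[i][j] = best;
    }
  }
  std::string db(n, '.');
  if (n == 0) return db;
  std::vector<std::pair<int, int> > todo;
  todo.push_back(std::make_pair(0, n - 1));
  while (!todo.empty()) {
    int i = todo.back().first, j = todo.back().second;
    todo.pop_back();
    if (i >= j || M[i][j] == 0) continue;
    if (!blocked[i] && !blocked[j] && can_pair(seq[i], seq[j]) &&
        j - i - 1 >= min_loop && M[i][j] == M[i + 1][j - 1] + 1) {
      db[i] = '(';
      db[j] = ')';
      todo.push_back(std::make_pair(i + 1, j - 1));
    } else if (M[i][j] == M[i + 1][j]) {
      todo.push_back(std::make_pair(i + 1, j));
    } else if (M[i][j] == M[i][j - 1]) {
      todo.push_back(std::make_pair(i, j - 1));
    } else {
      for (int k = i + 1; k < j; ++k) {
        if (M[i][k] + M[k + 1][j] == M[i][j]) {
          todo.push_back(std::make_pair(i, k));
          todo.push_back(std::make_pair(k + 1, j));
          break;
        }
      }
    }
  }
  return db;
}
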