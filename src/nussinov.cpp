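#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Pair weight used by the fallback folder: GC = 2, AU = 1, GU = 1, else 0.
// The surrogate "energy" is minus the total pair weight; it orders
// structures by stability but is not on the kcal/mol scale.
static inline int pair_weight(char a, char b) {
  if ((a == 'G' && b == 'C') || (a == 'C' && b == 'G')) return 2;
  if ((a == 'A' && b == 'T') || (a == 'T' && b == 'A')) return 1;
  if ((a == 'G' && b == 'T') || (a == 'T' && b == 'G')) return 1;
  return 0;
}

// Among equally scoring structures, prefer pairing position i (rather than
// leaving it unpaired) and prefer the most distant partner: this keeps long
// designed stems intact instead of rerouting pairs into terminal loops.
static void traceback(const std::string& s,
                      const std::vector<std::vector<int> >& M,
                      int i, int j, int min_loop, std::string& db) {
  if (j - i <= min_loop) return;
  for (int k = j; k >= i + min_loop + 1; --k) {
    int w = pair_weight(s[i], s[k]);
    if (w == 0) continue;
    int left = (k - i - 1 > min_loop) ? M[i + 1][k - 1] : 0;
    int right = (k < j) ? M[k + 1][j] : 0;
    if (M[i][j] == left + right + w) {
      db[i] = '(';
      db[k] = ')';
      traceback(s, M, i + 1, k - 1, min_loop, db);
      if (k < j) traceback(s, M, k + 1, j, min_loop, db);
      return;
    }
  }
  traceback(s, M, i + 1, j, min_loop, db);
}

//' @noRd
// [[Rcpp::export(name = ".nussinov_fold_cpp")]]
List nussinov_fold_cpp(std::string seq, int min_loop = 3) {
  int n = seq.size();
  std::string db(n, '.');
  if (n == 0) return List::create(_["structure"] = db, _["score"] = 0);
  std::vector<std::vector<int> > M(n, std::vector<int>(n, 0));
  for (int span = min_loop + 1; span < n; ++span) {
    for (int i = 0; i + span < n; ++i) {
      int j = i + span;
      int best = M[i + 1][j];
      for (int k = i + min_loop + 1; k <= j; ++k) {
        int w = pair_weight(seq[i], seq[k]);
        if (w == 0) continue;
        int left = (k - i - 1 > min_loop) ? M[i + 1][k - 1] : 0;
        int right = (k < j) ? M[k + 1][j] : 0;
        int cand = left + right + w;
        if (cand > best) best = cand;
      }
      M[i][j] = best;
    }
  }
  traceback(seq, M, 0, n - 1, min_loop, db);
  return List::create(_["structure"] = db, _["score"] = M[0][n - 1]);
}
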