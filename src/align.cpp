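#include <Rcpp.h>
#include <string>
#include <vector>

using namespace Rcpp;

// Global (Needleman-Wunsch) alignment with linear gap penalty.
// Scoring: match +1, mismatch -1, gap -1 per residue.
// Returns the optimal score and the maximum number of identical aligned
// positions over all score-optimal alignments (a second DP restricted to
// optimal transitions). Using the maximum makes the identity count
// symmetric in its arguments and independent of tie-breaking order.
static void nw_core(const std::string& a, const std::string& b,
                    int match, int mismatch, int gap,
                    int& score, int& identities) {
  const int n = a.size(), m = b.size();
  std::vector<std::vector<int> > S(n + 1, std::vector<int>(m + 1, 0));
  std::vector<std::vector<int> > I(n + 1, std::vector<int>(m + 1, 0));
  for (int i = 1; i <= n; ++i) S[i][0] = i * gap;
  for (int j = 1; j <= m; ++j) S[0][j] = j * gap;
  for (int i = 1; i <= n; ++i) {
    const char ai = a[i - 1];
    for (int j = 1; j <= m; ++j) {
      const bool eq = (ai == b[j - 1]);
      const int diag = S[i - 1][j - 1] + (eq ? match : mismatch);
      const int up   = S[i - 1][j] + gap;
      const int left = S[i][j - 1] + gap;
      int best = diag;
      if (up > best) best = up;
      if (left > best) best = left;
      S[i][j] = best;
      int ident = -1;
      if (diag == best) {
        const int cand = I[i - 1][j - 1] + (eq ? 1 : 0);
        if (cand > ident) ident = cand;
      }
      if (up == best && I[i - 1][j] > ident) ident = I[i - 1][j];
      if (left == best && I[i][j - 1] > ident) ident = I[i][j - 1];
      I[i][j] = ident;
    }
  }
  score = S[n][m];
  identities = I[n][m];
}

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(CharacterVector a, CharacterVector b,
                  int match = 1, int mismatch = -1, int gap = -1) {
  const int n = a.size();
  if (b.size() != n) stop("sequence vectors must have equal length");
  IntegerVector score(n), identities(n);
  for (int k = 0; k < n; ++k) {
    std::string sa = as<std::string>(a[k]);
    std::string sb = as<std::string>(b[k]);
    if (sa.empty() || sb.empty()) stop("sequences must be non-empty");
    int sc, id;
    nw_core(sa, sb, match, mismatch, gap, sc, id);
    score[k] = sc;
    identities[k] = id;
  }
  return List::create(_["score"] = score, _["identities"] = identities);
}
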