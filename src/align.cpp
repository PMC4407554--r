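#include <Rcpp.h>
#include <vector>
#include <string>
#include <limits>
using namespace Rcpp;

// Gotoh affine-gap global alignment with deterministic traceback.
// Gap of length L scores gap_open + (L - 1) * gap_extend.
// Tie preference at every cell and at traceback start: diagonal (M),
// then up (gap in b), then left (gap in a).

// [[Rcpp::export(name = ".nw_affine")]]
List nw_affine(std::string a, std::string b,
               double match, double mismatch,
               double gap_open, double gap_extend) {
  const int n = a.size(), m = b.size();
  const double NEG = -std::numeric_limits<double>::infinity();
  // state 0 = M (a[i] ~ b[j]), 1 = X (a[i] ~ gap, "up"), 2 = Y (gap ~ b[j], "left")
  std::vector<double> M((n + 1) * (m + 1), NEG);
  std::vector<double> X((n + 1) * (m + 1), NEG);
  std::vector<double> Y((n + 1) * (m + 1), NEG);
  // ptr[state][idx] = predecessor state
  std::vector<unsigned char> pM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> pX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> pY((n + 1) * (m + 1), 0);
  auto at = [m](int i, int j) { return i * (m + 1) + j; };

  M[at(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[at(i, 0)] = gap_open + (i - 1) * gap_extend;
    pX[at(i, 0)] = (i == 1) ? 0 : 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[at(0, j)] = gap_open + (j - 1) * gap_extend;
    pY[at(0, j)] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      const int ij = at(i, j);
      const double s = (a[i - 1] == b[j - 1]) ? match : mismatch;
      // M: from any state at (i-1, j-1); prefer M, X, Y on ties
      {
        const int p = at(i - 1, j - 1);
        double best = M[p]; unsigned char st = 0;
        if (X[p] > best) { best = X[p]; st = 1; }
        if (Y[p] > best) { best = Y[p]; st = 2; }
        M[ij] = best + s; pM[ij] = st;
      }
      // X: gap in b (consume a[i]); open from M/Y, extend from X
      {
        const int p = at(i - 1, j);
        double fromM = M[p] + gap_open;
        double fromX = X[p] + gap_extend;
        double fromY = Y[p] + gap_open;
        double best = fromM; unsigned char st = 0;
        if (fromX > best) { best = fromX; st = 1; }
        if (fromY > best) { best = fromY; st = 2; }
        X[ij] = best; pX[ij] = st;
      }
      // Y: gap in a (consume b[j])
      {
        const int p = at(i, j - 1);
        double fromM = M[p] + gap_open;
        double fromX = X[p] + gap_open;
        double fromY = Y[p] + gap_extend;
        double best = fromM; unsigned char st = 0;
        if (fromX > best) { best = fromX; st = 1; }
        if (fromY > best) { best = fromY; st = 2; }
        Y[ij] = best; pY[ij] = st;
      }
    }
  }

  const int e = at(n, m);
  double score = M[e]; unsigned char st = 0;
  if (X[e] > score) { score = X[e]; st = 1; }
  if (Y[e] > score) { score = Y[e]; st = 2; }

  std::string oa, ob;
  oa.reserve(n + m); ob.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const int ij = at(i, j);
    if (st == 0) {
      const unsigned char prev = pM[ij];
      oa.push_back(a[i - 1]); ob.push_back(b[j - 1]);
      --i; --j; st = prev;
    } else if (st == 1) {
      const unsigned char prev = pX[ij];
      oa.push_back(a[i - 1]); ob.push_back('-');
      --i; st = prev;
    } else {
      const unsigned char prev = pY[ij];
      oa.push_back('-'); ob.push_back(b[j - 1]);
      --j; st = prev;
    }
  }
  std::reverse(oa.begin(), oa.end());
  std::reverse(ob.begin(), ob.end());
  return List::create(_["aligned_a"] = oa, _["aligned_b"] = ob,
                      _["score"] = score);
}
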