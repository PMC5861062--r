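#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment (Needleman-Wunsch with Gotoh three-state
// recurrences) over a precomputed position-score matrix S (n1 x n2). A gap of
// length k costs gapOpen + k*gapExtend (BLAST convention). Returns the optimal
// score and the aligned index paths (1-based, 0 = gap), so the same kernel
// serves residue-vs-residue and profile-vs-profile steps of the progressive
// aligner. Traceback ties are broken deterministically: diagonal, then gap in
// the second sequence, then gap in the first.

// [[Rcpp::export(name = ".affineAlignGlobal")]]
List affineAlignGlobal(NumericMatrix S, double gapOpen, double gapExtend) {
  const int n1 = S.nrow(), n2 = S.ncol();
  const double NEG = -1e30;
  const double gi = gapOpen + gapExtend; // cost of the first gapped position

  std::vector<double> M((n1 + 1) * (n2 + 1), NEG);
  std::vector<double> X((n1 + 1) * (n2 + 1), NEG); // gap in seq2 (consume seq1)
  std::vector<double> Y((n1 + 1) * (n2 + 1), NEG); // gap in seq1 (consume seq2)
  const int W = n2 + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n1; ++i) X[IDX(i, 0)] = -(gapOpen + i * gapExtend);
  for (int j = 1; j <= n2; ++j) Y[IDX(0, j)] = -(gapOpen + j * gapExtend);

  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      X[IDX(i, j)] = std::max(
          std::max(M[IDX(i - 1, j)], Y[IDX(i - 1, j)]) - gi,
          X[IDX(i - 1, j)] - gapExtend);
      Y[IDX(i, j)] = std::max(
          std::max(M[IDX(i, j - 1)], X[IDX(i, j - 1)]) - gi,
          Y[IDX(i, j - 1)] - gapExtend);
      double prev = std::max(M[IDX(i - 1, j - 1)],
                    std::max(X[IDX(i - 1, j - 1)], Y[IDX(i - 1, j - 1)]));
      M[IDX(i, j)] = prev + S(i - 1, j - 1);
    }
  }

  int i = n1, j = n2, state;
  double m = M[IDX(i, j)], x = X[IDX(i, j)], y = Y[IDX(i, j)];
  double best = std::max(m, std::max(x, y));
  state = (best == m) ? 0 : (best == x ? 1 : 2);

  std::vector<int> p1, p2;
  while (i > 0 || j > 0) {
    if (i == 0) { p1.push_back(0); p2.push_back(j); --j; continue; }
    if (j == 0) { p1.push_back(i); p2.push_back(0); --i; continue; }
    if (state == 0) {
      p1.push_back(i); p2.push_back(j);
      double prevM = M[IDX(i - 1, j - 1)], prevX = X[IDX(i - 1, j - 1)],
             prevY = Y[IDX(i - 1, j - 1)];
      double prev = std::max(prevM, std::max(prevX, prevY));
      --i; --j;
      state = (prev == prevM) ? 0 : (prev == prevX ? 1 : 2);
    } else if (state == 1) {
      p1.push_back(i); p2.push_back(0);
      double viaOpen = std::max(M[IDX(i - 1, j)], Y[IDX(i - 1, j)]) - gi;
      double viaExt = X[IDX(i - 1, j)] - gapExtend;
      if (viaExt > viaOpen) { --i; state = 1; }
      else {
        double m0 = M[IDX(i - 1, j)], y0 = Y[IDX(i - 1, j)];
        --i; state = (m0 >= y0) ? 0 : 2;
      }
    } else {
      p1.push_back(0); p2.push_back(j);
      double viaOpen = std::max(M[IDX(i, j - 1)], X[IDX(i, j - 1)]) - gi;
      double viaExt = Y[IDX(i, j - 1)] - gapExtend;
      if (viaExt > viaOpen) { --j; state = 2; }
      else {
        double m0 = M[IDX(i, j - 1)], x0 = X[IDX(i, j - 1)];
        --j; state = (m0 >= x0) ? 0 : 1;
      }
    }
  }
#undef IDX

  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());
  return List::create(_["score"] = best,
                      _["path1"] = wrap(p1),
                      _["path2"] = wrap(p2));
}
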