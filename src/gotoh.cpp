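#include <Rcpp.h>
using namespace Rcpp;

// Affine-gap global alignment (Gotoh three-state DP) over a precomputed
// column-score matrix S, where S(i, j) is the score of pairing row unit i of
// sequence/profile A with column unit j of B.  A gap of length k costs
// open + k * ext.  Traceback tie order is fixed: diagonal > up (consume A,
// gap in B) > left (consume B, gap in A), giving a bit-reproducible path.
//
// Returns the optimal score plus two equal-length index vectors (1-based,
// 0 = gap) describing the aligned path.
// [[Rcpp::export]]
List gotoh_align_cpp(NumericMatrix S, double open, double ext) {
  const int n = S.nrow(), m = S.ncol();
  const double NEG = -1e30;

  // state codes: 0 = M (diagonal), 1 = X (up, gap in B), 2 = Y (left, gap in A)
  NumericMatrix M(n + 1, m + 1), X(n + 1, m + 1), Y(n + 1, m + 1);
  IntegerMatrix tbM(n + 1, m + 1), tbX(n + 1, m + 1), tbY(n + 1, m + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = -(open + ext * i);
    tbX(i, 0) = 1;
  }
  for (int j = 1; j <= m; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = -(open + ext * j);
    tbY(0, j) = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M: tie preference M > X > Y
      double bm = M(i - 1, j - 1); int pm = 0;
      if (X(i - 1, j - 1) > bm) { bm = X(i - 1, j - 1); pm = 1; }
      if (Y(i - 1, j - 1) > bm) { bm = Y(i - 1, j - 1); pm = 2; }
      M(i, j) = bm + S(i - 1, j - 1);
      tbM(i, j) = pm;

      double xo = M(i - 1, j) - (open + ext);
      double xe = X(i - 1, j) - ext;
      if (xo >= xe) { X(i, j) = xo; tbX(i, j) = 0; }
      else          { X(i, j) = xe; tbX(i, j) = 1; }

      double yo = M(i, j - 1) - (open + ext);
      double ye = Y(i, j - 1) - ext;
      if (yo >= ye) { Y(i, j) = yo; tbY(i, j) = 0; }
      else          { Y(i, j) = ye; tbY(i, j) = 2; }
    }
  }

  int state = 0;
  double best = M(n, m);
  if (X(n, m) > best) { best = X(n, m); state = 1; }
  if (Y(n, m) > best) { best = Y(n, m); state = 2; }

  std::vector<int> ai, bi;
  int i = n, j = m;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM(i, j);
      ai.push_back(i); bi.push_back(j);
      --i; --j;
      state = prev;
    } else if (state == 1) {
      int prev = tbX(i, j);
      ai.push_back(i); bi.push_back(0);
      --i;
      state = prev;
    } else {
      int prev = tbY(i, j);
      ai.push_back(0); bi.push_back(j);
      --j;
      state = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = best,
                      _["a_idx"] = wrap(ai),
                      _["b_idx"] = wrap(bi));
}
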