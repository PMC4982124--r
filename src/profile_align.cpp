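#include <Rcpp.h>
using namespace Rcpp;

// Global affine-gap alignment over a precomputed column-column score
// matrix C (n1 x n2). A gap run of length L costs gap_open + L * gap_extend
// (both arguments are negative scores). Returns the optimal score and the
// aligned column paths (1-based column indices, 0 = gap), used both for
// pairwise sequence alignment and for profile-profile merges in the
// progressive aligner.
// [[Rcpp::export]]
List affine_align_path(NumericMatrix C, double gap_open, double gap_extend) {
  const int n1 = C.nrow(), n2 = C.ncol();
  const double NEG = -1e30;
  // state 0 = M (match), 1 = X (gap in profile 2), 2 = Y (gap in profile 1)
  NumericMatrix M(n1 + 1, n2 + 1), X(n1 + 1, n2 + 1), Y(n1 + 1, n2 + 1);
  IntegerMatrix tbM(n1 + 1, n2 + 1), tbX(n1 + 1, n2 + 1), tbY(n1 + 1, n2 + 1);

  M(0, 0) = 0.0; X(0, 0) = NEG; Y(0, 0) = NEG;
  for (int i = 1; i <= n1; ++i) {
    M(i, 0) = NEG; Y(i, 0) = NEG;
    X(i, 0) = gap_open + i * gap_extend;
    tbX(i, 0) = 1;
  }
  for (int j = 1; j <= n2; ++j) {
    M(0, j) = NEG; X(0, j) = NEG;
    Y(0, j) = gap_open + j * gap_extend;
    tbY(0, j) = 2;
  }
  for (int i = 1; i <= n1; ++i) {
    for (int j = 1; j <= n2; ++j) {
      // M: consume column i of profile 1 and column j of profile 2
      double m0 = M(i - 1, j - 1), m1 = X(i - 1, j - 1), m2 = Y(i - 1, j - 1);
      int am = 0; double bm = m0;
      if (m1 > bm) { bm = m1; am = 1; }
      if (m2 > bm) { bm = m2; am = 2; }
      M(i, j) = bm + C(i - 1, j - 1); tbM(i, j) = am;
      // X: consume column i of profile 1 against a gap
      double x0 = M(i - 1, j) + gap_open + gap_extend;
      double x1 = X(i - 1, j) + gap_extend;
      double x2 = Y(i - 1, j) + gap_open + gap_extend;
      int ax = 0; double bx = x0;
      if (x1 > bx) { bx = x1; ax = 1; }
      if (x2 > bx) { bx = x2; ax = 2; }
      X(i, j) = bx; tbX(i, j) = ax;
      // Y: consume column j of profile 2 against a gap
      double y0 = M(i, j - 1) + gap_open + gap_extend;
      double y1 = X(i, j - 1) + gap_open + gap_extend;
      double y2 = Y(i, j - 1) + gap_extend;
      int ay = 0; double by = y0;
      if (y1 > by) { by = y1; ay = 1; }
      if (y2 > by) { by = y2; ay = 2; }
      Y(i, j) = by; tbY(i, j) = ay;
    }
  }
  int state = 0;
  double best = M(n1, n2);
  if (X(n1, n2) > best) { best = X(n1, n2); state = 1; }
  if (Y(n1, n2) > best) { best = Y(n1, n2); state = 2; }

  std::vector<int> p1, p2;
  int i = n1, j = n2;
  while (i > 0 || j > 0) {
    if (state == 0) {
      int prev = tbM(i, j);
      p1.push_back(i); p2.push_back(j);
      --i; --j; state = prev;
    } else if (state == 1) {
      int prev = tbX(i, j);
      p1.push_back(i); p2.push_back(0);
      --i; state = prev;
    } else {
      int prev = tbY(i, j);
      p1.push_back(0); p2.push_back(j);
      --j; state = prev;
    }
  }
  std::reverse(p1.begin(), p1.end());
  std::reverse(p2.begin(), p2.end());
  return List::create(_["score"] = best,
                      _["path1"] = IntegerVector(p1.begin(), p1.end()),
                      _["path2"] = IntegerVector(p2.begin(), p2.end()));
}
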