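#include <Rcpp.h>
using namespace Rcpp;

// Profile-profile global alignment with affine gaps (Gotoh).
// Profiles are 5 x L count matrices, rows A,C,G,T,gap.  Column-column
// score is the average pairwise substitution score over non-gap residues;
// residue-vs-existing-gap pairs score 0.  Returns the traceback as two
// integer vectors: for each output column, the source column (1-based) in
// A and in B, or 0 for a gap.
//
// DP values use rolling rows; traceback states (0=M diagonal, 1=X consume
// an A column against a gap, 2=Y consume a B column) are stored in full.
// [[Rcpp::export]]
List profile_align_cpp(NumericMatrix A, NumericMatrix B,
                       double match, double mismatch,
                       double gap_open, double gap_extend) {
  const int n = A.ncol(), m = B.ncol();
  const double NEG = -1e18;

  // contiguous copies: 4 base counts per column + total
  std::vector<double> a(4 * n), b(4 * m), tA(n), tB(m);
  for (int i = 0; i < n; ++i) {
    double t = 0;
    for (int k = 0; k < 4; ++k) { a[4*i+k] = A(k, i); t += A(k, i); }
    tA[i] = t;
  }
  for (int j = 0; j < m; ++j) {
    double t = 0;
    for (int k = 0; k < 4; ++k) { b[4*j+k] = B(k, j); t += B(k, j); }
    tB[j] = t;
  }

  std::vector<double> Mp(m+1), Xp(m+1), Yp(m+1), Mc(m+1), Xc(m+1), Yc(m+1);
  std::vector<unsigned char> tM((size_t)(n+1)*(m+1)),
                             tX((size_t)(n+1)*(m+1)),
                             tY((size_t)(n+1)*(m+1));
  const size_t W = m + 1;

  Mp[0] = 0.0; Xp[0] = Yp[0] = NEG;
  for (int j = 1; j <= m; ++j) {
    Mp[j] = NEG; Xp[j] = NEG;
    Yp[j] = gap_open + gap_extend * (j - 1);
    tY[j] = (j == 1) ? 0 : 2;
  }

  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG; Yc[0] = NEG;
    Xc[0] = gap_open + gap_extend * (i - 1);
    tX[(size_t)i*W] = (i == 1) ? 0 : 1;
    const double *ai = &a[4*(size_t)(i-1)];
    const double tai = tA[i-1];
    for (int j = 1; j <= m; ++j) {
      const double *bj = &b[4*(size_t)(j-1)];
      double same = ai[0]*bj[0] + ai[1]*bj[1] + ai[2]*bj[2] + ai[3]*bj[3];
      double pairs = tai * tB[j-1];
      double sc = pairs > 0 ?
        (match * same + mismatch * (pairs - same)) / pairs : 0.0;
      const size_t idx = (size_t)i*W + j;
      // M from diagonal (i-1, j-1)
      double v = Mp[j-1]; unsigned char st = 0;
      if (Xp[j-1] > v) { v = Xp[j-1]; st = 1; }
      if (Yp[j-1] > v) { v = Yp[j-1]; st = 2; }
      Mc[j] = v + sc; tM[idx] = st;
      // X from (i-1, j)
      v = Mp[j] + gap_open; st = 0;
      if (Xp[j] + gap_extend > v) { v = Xp[j] + gap_extend; st = 1; }
      if (Yp[j] + gap_open > v) { v = Yp[j] + gap_open; st = 2; }
      Xc[j] = v; tX[idx] = st;
      // Y from (i, j-1)
      v = Mc[j-1] + gap_open; st = 0;
      if (Xc[j-1] + gap_open > v) { v = Xc[j-1] + gap_open; st = 1; }
      if (Yc[j-1] + gap_extend > v) { v = Yc[j-1] + gap_extend; st = 2; }
      Yc[j] = v; tY[idx] = st;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }

  int state = 0; double best = Mp[m];
  if (Xp[m] > best) { best = Xp[m]; state = 1; }
  if (Yp[m] > best) { best = Yp[m]; state = 2; }
  std::vector<int> ia, ib;
  ia.reserve(n + m); ib.reserve(n + m);
  int i = n, j = m;
  while (i > 0 || j > 0) {
    const size_t idx = (size_t)i*W + j;
    if (state == 0) {
      ia.push_back(i); ib.push_back(j);
      state = tM[idx]; --i; --j;
    } else if (state == 1) {
      ia.push_back(i); ib.push_back(0);
      state = tX[idx]; --i;
    } else {
      ia.push_back(0); ib.push_back(j);
      state = tY[idx]; --j;
    }
  }
  std::reverse(ia.begin(), ia.end());
  std::reverse(ib.begin(), ib.end());
  return List::create(_["a"] = wrap(ia), _["b"] = wrap(ib),
                      _["score"] = best);
}
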