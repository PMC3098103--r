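#include <Rcpp.h>
using namespace Rcpp;

// Gotoh affine-gap global alignment over a precomputed pair-score matrix.
// A gap of length L costs open + L * ext.  With free_ends, terminal gaps in
// either sequence are not penalised (EMBOSS needle endweight=false).
//
// S: n x m matrix, S(i,j) = score of pairing a[i] with b[j].
// Returns list(score, ai, bi): ai/bi are 1-based indices per alignment
// column, 0 where that column is a gap in the respective sequence.

static const double NEG_INF = -1e300;

// [[Rcpp::export(name = ".nw_align_cpp")]]
List nw_align_cpp(NumericMatrix S, double gap_open, double gap_ext,
                  bool free_ends) {
  const int n = S.nrow(), m = S.ncol();
  if (n < 1 || m < 1) stop("empty sequence in alignment");

  const double gi = gap_open + gap_ext;  // cost of opening (first gap column)
  const double ge = gap_ext;             // cost of extending

  // state 0 = M (pair), 1 = X (gap in b, consumes a), 2 = Y (gap in a)
  std::vector<double> M((n + 1) * (m + 1), NEG_INF);
  std::vector<double> X((n + 1) * (m + 1), NEG_INF);
  std::vector<double> Y((n + 1) * (m + 1), NEG_INF);
  std::vector<unsigned char> pM((n + 1) * (m + 1), 0);
  std::vector<unsigned char> pX((n + 1) * (m + 1), 0);
  std::vector<unsigned char> pY((n + 1) * (m + 1), 0);
  const int W = m + 1;
#define IDX(i, j) ((i) * W + (j))

  M[IDX(0, 0)] = 0.0;
  for (int i = 1; i <= n; ++i) {
    X[IDX(i, 0)] = free_ends ? 0.0 : -(gap_open + i * gap_ext);
    pX[IDX(i, 0)] = 1;
  }
  for (int j = 1; j <= m; ++j) {
    Y[IDX(0, j)] = free_ends ? 0.0 : -(gap_open + j * gap_ext);
    pY[IDX(0, j)] = 2;
  }

  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      // M
      double bm = M[IDX(i - 1, j - 1)];
      unsigned char pb = 0;
      if (X[IDX(i - 1, j - 1)] > bm) { bm = X[IDX(i - 1, j - 1)]; pb = 1; }
      if (Y[IDX(i - 1, j - 1)] > bm) { bm = Y[IDX(i - 1, j - 1)]; pb = 2; }
      M[IDX(i, j)] = bm + S(i - 1, j - 1);
      pM[IDX(i, j)] = pb;
      // X: consume a[i], gap in b
      double vx = M[IDX(i - 1, j)] - gi;
      unsigned char px = 0;
      if (X[IDX(i - 1, j)] - ge > vx) { vx = X[IDX(i - 1, j)] - ge; px = 1; }
      if (Y[IDX(i - 1, j)] - gi > vx) { vx = Y[IDX(i - 1, j)] - gi; px = 2; }
      X[IDX(i, j)] = vx;
      pX[IDX(i, j)] = px;
      // Y: consume b[j], gap in a
      double vy = M[IDX(i, j - 1)] - gi;
      unsigned char py = 0;
      if (Y[IDX(i, j - 1)] - ge > vy) { vy = Y[IDX(i, j - 1)] - ge; py = 2; }
      if (X[IDX(i, j - 1)] - gi > vy) { vy = X[IDX(i, j - 1)] - gi; py = 1; }
      Y[IDX(i, j)] = vy;
      pY[IDX(i, j)] = py;
    }
  }

  // termination: with free ends the best cell may sit on the last row or
  // column, trailing gaps appended at no cost.
  int bi_ = n, bj_ = m;
  unsigned char bs = 0;
  double best;
  auto cellbest = [&](int i, int j, unsigned char &st) {
    double v = M[IDX(i, j)];
    st = 0;
    if (X[IDX(i, j)] > v) { v = X[IDX(i, j)]; st = 1; }
    if (Y[IDX(i, j)] > v) { v = Y[IDX(i, j)]; st = 2; }
    return v;
  };
  best = cellbest(n, m, bs);
  if (free_ends) {
    for (int i = 0; i < n; ++i) {
      unsigned char st;
      double v = cellbest(i, m, st);
      if (v > best) { best = v; bi_ = i; bj_ = m; bs = st; }
    }
    for (int j = 0; j < m; ++j) {
      unsigned char st;
      double v = cellbest(n, j, st);
      if (v > best) { best = v; bi_ = n; bj_ = j; bs = st; }
    }
  }

  // traceback
  std::vector<int> ai, bi;
  ai.reserve(n + m);
  bi.reserve(n + m);
  // trailing free gaps
  for (int i = n; i > bi_; --i) { ai.push_back(i); bi.push_back(0); }
  for (int j = m; j > bj_; --j) { ai.push_back(0); bi.push_back(j); }
  int i = bi_, j = bj_;
  unsigned char st = bs;
  while (i > 0 || j > 0) {
    if (st == 0) {
      unsigned char prev = pM[IDX(i, j)];
      ai.push_back(i); bi.push_back(j);
      --i; --j; st = prev;
    } else if (st == 1) {
      unsigned char prev = pX[IDX(i, j)];
      ai.push_back(i); bi.push_back(0);
      --i; st = prev;
    } else {
      unsigned char prev = pY[IDX(i, j)];
      ai.push_back(0); bi.push_back(j);
      --j; st = prev;
    }
  }
  std::reverse(ai.begin(), ai.end());
  std::reverse(bi.begin(), bi.end());

  return List::create(_["score"] = best,
                      _["ai"] = IntegerVector(ai.begin(), ai.end()),
                      _["bi"] = IntegerVector(bi.begin(), bi.end()));
}

// Score-only variant over integer-coded sequences (1-based codes into sub),
// rolling arrays, no traceback: used for guide-tree distance matrices.
// [[Rcpp::export(name = ".nw_score_codes_cpp")]]
double nw_score_codes_cpp(IntegerVector a, IntegerVector b,
                          NumericMatrix sub, double gap_open, double gap_ext,
                          bool free_ends) {
  const int n = a.size(), m = b.size();
  if (n < 1 || m < 1) stop("empty sequence in alignment");
  const double gi = gap_open + gap_ext, ge = gap_ext;
  std::vector<double> Mp(m + 1, NEG_INF), Xp(m + 1, NEG_INF),
      Yp(m + 1, NEG_INF), Mc(m + 1), Xc(m + 1), Yc(m + 1);
  Mp[0] = 0.0;
  for (int j = 1; j <= m; ++j) Yp[j] = free_ends ? 0.0 : -(gap_open + j * ge);
  double best = NEG_INF;
  for (int i = 1; i <= n; ++i) {
    Mc[0] = NEG_INF;
    Yc[0] = NEG_INF;
    Xc[0] = free_ends ? 0.0 : -(gap_open + i * ge);
    const int ai = a[i - 1] - 1;
    for (int j = 1; j <= m; ++j) {
      double diag = std::max(Mp[j - 1], std::max(Xp[j - 1], Yp[j - 1]));
      Mc[j] = diag + sub(ai, b[j - 1] - 1);
      Xc[j] = std::max(Mp[j] - gi, std::max(Xp[j] - ge, Yp[j] - gi));
      Yc[j] = std::max(Mc[j - 1] - gi, std::max(Yc[j - 1] - ge, Xc[j - 1] - gi));
    }
    if (free_ends) {
      double rowbest = std::max(Mc[m], std::max(Xc[m], Yc[m]));
      if (rowbest > best) best = rowbest;
    }
    std::swap(Mp, Mc); std::swap(Xp, Xc); std::swap(Yp, Yc);
  }
  double last = std::max(Mp[m], std::max(Xp[m], Yp[m]));
  if (!free_ends) return last;
  if (last > best) best = last;
  for (int j = 0; j < m; ++j) {
    double v = std::max(Mp[j], std::max(Xp[j], Yp[j]));
    if (v > best) best = v;
  }
  return best;
}
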