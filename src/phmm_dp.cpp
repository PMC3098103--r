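#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Profile-HMM dynamic programming (Viterbi / forward) in log-odds space.
//
// Node layout (Durbin-style): nodes 0..M; M_0 is the non-emitting begin
// state, the end state sits after node M.  Match node k (k = 1..M) emits
// with log-odds em(a, k-1); insert node k (k = 0..M) emits with log-odds
// ei(a, k).  Transition vectors are indexed by source node k:
//   tMM[k]: M_k -> M_{k+1} (k = M means M_M -> end), tMI[k]: M_k -> I_k,
//   tMD[k]: M_k -> D_{k+1}; analogously tIM/tII/tID from I_k and
//   tDM/tDI/tDD from D_k (D defined for k = 1..M).
// seq: residue indices 0..19; -1 encodes an ambiguous residue whose
// emission log-odds is 0 (scores as background).

static inline double lse(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}
static inline double lse3(double a, double b, double c) {
  return lse(lse(a, b), c);
}
static inline double max3(double a, double b, double c) {
  return std::max(a, std::max(b, c));
}

// [[Rcpp::export(name = ".phmm_score_cpp")]]
double phmm_score_cpp(NumericMatrix em, NumericMatrix ei,
                      NumericVector tMM, NumericVector tMI, NumericVector tMD,
                      NumericVector tIM, NumericVector tII, NumericVector tID,
                      NumericVector tDM, NumericVector tDI, NumericVector tDD,
                      IntegerVector seq, bool viterbi) {
  const int M = em.ncol();
  const int L = seq.size();
  if (M < 1) stop("model has no match states");
  if (L < 1) stop("empty sequence");

  // columns over nodes, two sequence positions (prev = i-1, cur = i)
  std::vector<double> vMp(M + 1, R_NegInf), vIp(M + 1, R_NegInf),
      vDp(M + 1, R_NegInf);
  std::vector<double> vMc(M + 1), vIc(M + 1), vDc(M + 1);

  // i = 0: begin at M_0; deletes can run along the top row silently
  vMp[0] = 0.0;
  for (int k = 1; k <= M; ++k) {
    double fromM = vMp[k - 1] + tMD[k - 1];
    double fromI = vIp[k - 1] + tID[k - 1];
    double fromD = (k >= 2) ? vDp[k - 1] + tDD[k - 1] : R_NegInf;
    vDp[k] = viterbi ? max3(fromM, fromI, fromD) : lse3(fromM, fromI, fromD);
  }

  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    for (int k = 0; k <= M; ++k) {
      vMc[k] = vIc[k] = vDc[k] = R_NegInf;
    }
    for (int k = 0; k <= M; ++k) {
      // insert k (emits a)
      double e = (a < 0) ? 0.0 : ei(a, k);
      double m = vMp[k] + tMI[k];
      double ii = vIp[k] + tII[k];
      double d = (k >= 1) ? vDp[k] + tDI[k] : R_NegInf;
      vIc[k] = e + (viterbi ? max3(m, ii, d) : lse3(m, ii, d));
      if (k >= 1) {
        // match k (emits a)
        double eM = (a < 0) ? 0.0 : em(a, k - 1);
        double mm = vMp[k - 1] + tMM[k - 1];
        double im = vIp[k - 1] + tIM[k - 1];
        double dm = (k >= 2) ? vDp[k - 1] + tDM[k - 1] : R_NegInf;
        vMc[k] = eM + (viterbi ? max3(mm, im, dm) : lse3(mm, im, dm));
      }
    }
    // deletes at position i (silent; depend on current column, ascending k)
    for (int k = 1; k <= M; ++k) {
      double fromM = vMc[k - 1] + tMD[k - 1];
      double fromI = vIc[k - 1] + tID[k - 1];
      double fromD = (k >= 2) ? vDc[k - 1] + tDD[k - 1] : R_NegInf;
      vDc[k] = viterbi ? max3(fromM, fromI, fromD) : lse3(fromM, fromI, fromD);
    }
    std::swap(vMp, vMc);
    std::swap(vIp, vIc);
    std::swap(vDp, vDc);
  }

  double endM = vMp[M] + tMM[M];
  double endI = vIp[M] + tIM[M];
  double endD = vDp[M] + tDM[M];
  return viterbi ? max3(endM, endI, endD) : lse3(endM, endI, endD);
}
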