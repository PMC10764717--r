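#include <Rcpp.h>
#include <cmath>
#include <limits>

// Plan7-like profile DP in log space. Emissions arrive as log-odds
// (log e(x)/bg(x)); insert/flank emissions likewise, so the null model is
// implicit and the returned value is the natural-log odds of the sequence.
//
// Transition matrix layout: (M+1) x 7, rows are nodes 0..M (node 0 = begin),
// columns MM MI MD IM II DM DD, natural-log probabilities. At node M the
// MM/MD mass routes to the end state, D_M exits with probability 1 and
// I_M exits via its IM component.

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// [[Rcpp::export]]
double cpp_forward_glocal(Rcpp::NumericMatrix logE, Rcpp::NumericVector logEins,
                          Rcpp::NumericMatrix logT) {
  const int M = logE.nrow();
  const int L = logE.ncol();
  std::vector<double> Mp(M + 1, NEG_INF), Ip(M + 1, NEG_INF), Dp(M + 1, NEG_INF);
  std::vector<double> Mc(M + 1), Ic(M + 1), Dc(M + 1);

  // i = 0: begin occupied, delete chain reachable without emitting
  Mp[0] = 0.0;
  Dp[1] = logT(0, 2);                       // B -> D1
  for (int j = 2; j <= M; ++j) Dp[j] = Dp[j - 1] + logT(j - 1, 6);

  for (int i = 1; i <= L; ++i) {
    Mc[0] = NEG_INF;
    Dc[0] = NEG_INF;
    Ic[0] = logEins[i - 1] + lse2(Mp[0] + logT(0, 1), Ip[0] + logT(0, 4));
    for (int j = 1; j <= M; ++j) {
      Mc[j] = logE(j - 1, i - 1) +
              lse3(Mp[j - 1] + logT(j - 1, 0),
                   Ip[j - 1] + logT(j - 1, 3),
                   Dp[j - 1] + logT(j - 1, 5));
      Ic[j] = logEins[i - 1] + lse2(Mp[j] + logT(j, 1), Ip[j] + logT(j, 4));
      Dc[j] = lse2(Mc[j - 1] + logT(j - 1, 2), Dc[j - 1] + logT(j - 1, 6));
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }

  double tME = lse2(logT(M, 0), logT(M, 2));   // M_M -> E uses MM + MD mass
  return lse3(Mp[M] + tME, Ip[M] + logT(M, 3), Dp[M]);
}

// [[Rcpp::export]]
double cpp_forward_local(Rcpp::NumericMatrix logE, Rcpp::NumericVector logEins,
                         Rcpp::NumericMatrix logT) {
  const int M = logE.nrow();
  const int L = logE.ncol();
  const double logEntry = -std::log((double) M);
  const double logExit  = -std::log((double) M);
  std::vector<double> Mp(M + 1, NEG_INF), Ip(M + 1, NEG_INF), Dp(M + 1, NEG_INF);
  std::vector<double> Mc(M + 1, NEG_INF), Ic(M + 1, NEG_INF), Dc(M + 1, NEG_INF);
  double total = NEG_INF;

  for (int i = 1; i <= L; ++i) {
    Mc[0] = Ic[0] = Dc[0] = NEG_INF;
    for (int j = 1; j <= M; ++j) {
      double cont = lse3(Mp[j - 1] + logT(j - 1, 0),
                         Ip[j - 1] + logT(j - 1, 3),
                         Dp[j - 1] + logT(j - 1, 5));
      Mc[j] = logE(j - 1, i - 1) + lse2(logEntry, cont);
      Ic[j] = logEins[i - 1] + lse2(Mp[j] + logT(j, 1), Ip[j] + logT(j, 4));
      Dc[j] = lse2(Mc[j - 1] + logT(j - 1, 2), Dc[j - 1] + logT(j - 1, 6));
      total = lse2(total, Mc[j] + logExit);
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
  }
  return total;
}

// [[Rcpp::export]]
Rcpp::List cpp_viterbi_local(Rcpp::NumericMatrix logE, Rcpp::NumericVector logEins,
                             Rcpp::NumericMatrix logT) {
  const int M = logE.nrow();
  const int L = logE.ncol();
  const double logEntry = -std::log((double) M);
  const double logExit  = -std::log((double) M);
  std::vector<double> Mp(M + 1, NEG_INF), Ip(M + 1, NEG_INF), Dp(M + 1, NEG_INF);
  std::vector<double> Mc(M + 1, NEG_INF), Ic(M + 1, NEG_INF), Dc(M + 1, NEG_INF);
  // start-of-window (0-based residue index) carried along the best path
  std::vector<int> SMp(M + 1, -1), SIp(M + 1, -1), SDp(M + 1, -1);
  std::vector<int> SMc(M + 1, -1), SIc(M + 1, -1), SDc(M + 1, -1);

  double best = NEG_INF;
  int best_start = -1, best_end = -1;

  for (int i = 1; i <= L; ++i) {
    Mc[0] = Ic[0] = Dc[0] = NEG_INF;
    SMc[0] = SIc[0] = SDc[0] = -1;
    for (int j = 1; j <= M; ++j) {
      double fromM = Mp[j - 1] + logT(j - 1, 0);
      double fromI = Ip[j - 1] + logT(j - 1, 3);
      double fromD = Dp[j - 1] + logT(j - 1, 5);
      double m = logEntry; int src = 0;                  // 0 = fresh entry
      if (fromM > m) { m = fromM; src = 1; }
      if (fromI > m) { m = fromI; src = 2; }
      if (fromD > m) { m = fromD; src = 3; }
      Mc[j] = logE(j - 1, i - 1) + m;
      SMc[j] = src == 0 ? (i - 1) : (src == 1 ? SMp[j - 1] : (src == 2 ? SIp[j - 1] : SDp[j - 1]));

      double ifromM = Mp[j] + logT(j, 1);
      double ifromI = Ip[j] + logT(j, 4);
      if (ifromM >= ifromI) { Ic[j] = logEins[i - 1] + ifromM; SIc[j] = SMp[j]; }
      else                  { Ic[j] = logEins[i - 1] + ifromI; SIc[j] = SIp[j]; }

      double dfromM = Mc[j - 1] + logT(j - 1, 2);
      double dfromD = Dc[j - 1] + logT(j - 1, 6);
      if (dfromM >= dfromD) { Dc[j] = dfromM; SDc[j] = SMc[j - 1]; }
      else                  { Dc[j] = dfromD; SDc[j] = SDc[j - 1]; }

      double cand = Mc[j] + logExit;
      if (cand > best) { best = cand; best_start = SMc[j]; best_end = i; }
    }
    std::swap(Mp, Mc); std::swap(Ip, Ic); std::swap(Dp, Dc);
    std::swap(SMp, SMc); std::swap(SIp, SIc); std::swap(SDp, SDc);
  }
  return Rcpp::List::create(Rcpp::Named("log_odds") = best,
                            Rcpp::Named("start") = best_start,
                            Rcpp::Named("end") = best_end);
}
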