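// Forward and Viterbi dynamic programming for a glocal profile HMM
// (global in the profile, local in the sequence), scored in log-odds
// against an i.i.d. background null. Flanking residues are emitted by
// N/C states with background emission, so their log-odds contribution
// is zero; entry into the profile is allowed at every sequence position
// and exit at every position after the last match/delete state.
//
// All values are natural-log odds; conversion to bits happens in R.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <limits>

using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  double m = a > b ? a : b;
  return m + std::log1p(std::exp(-(std::fabs(a - b))));
}

static inline double lse3(double a, double b, double c) {
  return lse2(lse2(a, b), c);
}

// x: 1-based residue codes (0 = unknown -> emission odds 0)
// logE: m x 20 matrix of log(e_match / q)
// transition vectors are length m-1 (from state k to k+1, 1-based)
// [[Rcpp::export(name = ".dp_profile")]]
List dp_profile(IntegerVector x, NumericMatrix logE,
                double lBM, double lBD,
                NumericVector lMM, NumericVector lMI, NumericVector lMD,
                NumericVector lIM, NumericVector lII,
                NumericVector lDM, NumericVector lDD,
                bool do_path) {
  const int m = logE.nrow();
  const int L = x.size();

  std::vector<double> fM(m, NEG_INF), fI(m, NEG_INF), fD(m, NEG_INF);
  std::vector<double> nM(m), nI(m), nD(m);
  std::vector<double> vM(m, NEG_INF), vI(m, NEG_INF), vD(m, NEG_INF);
  std::vector<double> wM(m), wI(m), wD(m);

  // back pointers (only filled when do_path)
  std::vector<signed char> bpM, bpI, bpD, bpE;
  if (do_path) {
    bpM.assign((size_t)m * (L + 1), 0);
    bpI.assign((size_t)m * (L + 1), 0);
    bpD.assign((size_t)m * (L + 1), 0);
    bpE.assign(L + 1, 0);
  }
  auto IDX = [m](int k, int j) { return (size_t)j * m + k; };

  // j = 0: only an all-delete traversal is possible.
  fD[0] = lBD; vD[0] = lBD;
  if (do_path) bpD[IDX(0, 0)] = 3;
  for (int k = 1; k < m; ++k) {
    fD[k] = fD[k - 1] + lDD[k - 1];
    vD[k] = vD[k - 1] + lDD[k - 1];
    if (do_path) bpD[IDX(k, 0)] = 2;
  }

  double fwdTotal = lse2(fM[m - 1], fD[m - 1]);
  double vitBest = vD[m - 1] > vM[m - 1] ? vD[m - 1] : vM[m - 1];
  int vitJ = 0;
  if (do_path) bpE[0] = 2;

  for (int j = 1; j <= L; ++j) {
    const int xi = x[j - 1];  // 1-based code, 0 = unknown
    for (int k = 0; k < m; ++k) {
      const double e = (xi > 0) ? logE(k, xi - 1) : 0.0;
      if (k == 0) {
        nM[0] = lBM + e;
        wM[0] = lBM + e;
        if (do_path) bpM[IDX(0, j)] = 4;
      } else {
        double a = fM[k - 1] + lMM[k - 1];
        double b = fI[k - 1] + lIM[k - 1];
        double c = fD[k - 1] + lDM[k - 1];
        nM[k] = e + lse3(a, b, c);
        double va = vM[k - 1] + lMM[k - 1];
        double vb = vI[k - 1] + lIM[k - 1];
        double vc = vD[k - 1] + lDM[k - 1];
        double best = va; signed char bp = 1;
        if (vb > best) { best = vb; bp = 2; }
        if (vc > best) { best = vc; bp = 3; }
        wM[k] = e + best;
        if (do_path) bpM[IDX(k, j)] = bp;
      }
    }
    for (int k = 0; k < m - 1; ++k) {
      // insert emission odds are zero (background emission)
      nI[k] = lse2(fM[k] + lMI[k], fI[k] + lII[k]);
      double va = vM[k] + lMI[k];
      double vb = vI[k] + lII[k];
      if (va >= vb) { wI[k] = va; if (do_path) bpI[IDX(k, j)] = 1; }
      else          { wI[k] = vb; if (do_path) bpI[IDX(k, j)] = 2; }
    }
    nD[0] = lBD; wD[0] = lBD;
    if (do_path) bpD[IDX(0, j)] = 3;
    for (int k = 1; k < m; ++k) {
      nD[k] = lse2(nM[k - 1] + lMD[k - 1], nD[k - 1] + lDD[k - 1]);
      double va = wM[k - 1] + lMD[k - 1];
      double vb = wD[k - 1] + lDD[k - 1];
      if (va >= vb) { wD[k] = va; if (do_path) bpD[IDX(k, j)] = 1; }
      else          { wD[k] = vb; if (do_path) bpD[IDX(k, j)] = 2; }
    }
    std::swap(fM, nM); std::swap(fI, nI); std::swap(fD, nD);
    std::swap(vM, wM); std::swap(vI, wI); std::swap(vD, wD);

    fwdTotal = lse2(fwdTotal, lse2(fM[m - 1], fD[m - 1]));
    double ve; signed char be;
    if (vM[m - 1] >= vD[m - 1]) { ve = vM[m - 1]; be = 1; }
    else                        { ve = vD[m - 1]; be = 2; }
    if (do_path) bpE[j] = be;
    if (ve > vitBest) { vitBest = ve; vitJ = j; }
  }

  List out = List::create(_["forward"] = fwdTotal, _["viterbi"] = vitBest);

  if (do_path) {
    IntegerVector path(L, 0);
    int j = vitJ;
    int k = m - 1;
    char st = bpE[j] == 1 ? 'M' : 'D';
    bool done = false;
    while (!done) {
      if (st == 'M') {
        path[j - 1] = k + 1;
        signed char bp = bpM[IDX(k, j)];
        if (bp == 4) { done = true; }
        else if (bp == 1) { st = 'M'; --k; --j; }
        else if (bp == 2) { st = 'I'; --k; --j; }
        else              { st = 'D'; --k; --j; }
      } else if (st == 'I') {
        path[j - 1] = -(k + 1);
        signed char bp = bpI[IDX(k, j)];
        st = (bp == 1) ? 'M' : 'I';
        --j;
      } else {  // 'D'
        signed char bp = bpD[IDX(k, j)];
        if (bp == 3) { done = true; }
        else if (bp == 1) { st = 'M'; --k; }
        else              { st = 'D'; --k; }
      }
    }
    out["path"] = path;
  }
  return out;
}

// Posterior-decoded (maximum expected accuracy) alignment path.
// Forward-backward posteriors of match-state emissions feed a monotone
// alignment DP; small-posterior matches are suppressed by `delta`.
// Returns a state path in the same encoding as the Viterbi path.
// [[Rcpp::export(name = ".dp_mac_path")]]
IntegerVector dp_mac_path(IntegerVector x, NumericMatrix logE,
                          double lBM, double lBD,
                          NumericVector lMM, NumericVector lMI,
                          NumericVector lMD,
                          NumericVector lIM, NumericVector lII,
                          NumericVector lDM, NumericVector lDD,
                          double delta) {
  const int m = logE.nrow();
  const int L = x.size();
  auto EM = [&](int k, int j) {  // log emission odds of x_j at match k
    int xi = x[j - 1];
    return (xi > 0) ? logE(k, xi - 1) : 0.0;
  };

  // forward matrices over (k, j)
  std::vector<double> fM((size_t)m * (L + 1), NEG_INF);
  std::vector<double> fI((size_t)m * (L + 1), NEG_INF);
  std::vector<double> fD((size_t)m * (L + 1), NEG_INF);
  auto IX = [m](int k, int j) { return (size_t)j * m + k; };

  fD[IX(0, 0)] = lBD;
  for (int k = 1; k < m; ++k)
    fD[IX(k, 0)] = fD[IX(k - 1, 0)] + lDD[k - 1];
  double total = fD[IX(m - 1, 0)];  // all-delete traversal

  for (int j = 1; j <= L; ++j) {
    fM[IX(0, j)] = lBM + EM(0, j);
    for (int k = 1; k < m; ++k) {
      fM[IX(k, j)] = EM(k, j) +
        lse3(fM[IX(k - 1, j - 1)] + lMM[k - 1],
             fI[IX(k - 1, j - 1)] + lIM[k - 1],
             fD[IX(k - 1, j - 1)] + lDM[k - 1]);
    }
    for (int k = 0; k < m - 1; ++k)
      fI[IX(k, j)] = lse2(fM[IX(k, j - 1)] + lMI[k],
                          fI[IX(k, j - 1)] + lII[k]);
    fD[IX(0, j)] = lBD;
    for (int k = 1; k < m; ++k)
      fD[IX(k, j)] = lse2(fM[IX(k - 1, j)] + lMD[k - 1],
                          fD[IX(k - 1, j)] + lDD[k - 1]);
    total = lse2(total, lse2(fM[IX(m - 1, j)], fD[IX(m - 1, j)]));
  }

  // backward matrices
  std::vector<double> bM((size_t)m * (L + 1), NEG_INF);
  std::vector<double> bI((size_t)m * (L + 1), NEG_INF);
  std::vector<double> bD((size_t)m * (L + 1), NEG_INF);
  for (int j = L; j >= 0; --j) {
    bM[IX(m - 1, j)] = 0.0;  // M_m -> E, remainder emitted by the C flank
    bD[IX(m - 1, j)] = 0.0;
    for (int k = m - 2; k >= 0; --k) {
      double t1 = (j < L) ? EM(k + 1, j + 1) + lMM[k] + bM[IX(k + 1, j + 1)]
                          : NEG_INF;
      double t2 = (j < L) ? lMI[k] + bI[IX(k, j + 1)] : NEG_INF;
      double t3 = lMD[k] + bD[IX(k + 1, j)];
      bM[IX(k, j)] = lse3(t1, t2, t3);
      double u1 = (j < L) ? EM(k + 1, j + 1) + lIM[k] + bM[IX(k + 1, j + 1)]
                          : NEG_INF;
      double u2 = (j < L) ? lII[k] + bI[IX(k, j + 1)] : NEG_INF;
      bI[IX(k, j)] = lse2(u1, u2);
      double v1 = (j < L) ? EM(k + 1, j + 1) + lDM[k] + bM[IX(k + 1, j + 1)]
                          : NEG_INF;
      double v2 = lDD[k] + bD[IX(k + 1, j)];
      bD[IX(k, j)] = lse2(v1, v2);
    }
  }

  // match posteriors
  std::vector<double> PP((size_t)m * (L + 1), 0.0);
  for (int j = 1; j <= L; ++j)
    for (int k = 0; k < m; ++k) {
      double lp = fM[IX(k, j)] + bM[IX(k, j)] - total;
      PP[IX(k, j)] = (lp > -40.0) ? std::exp(lp) : 0.0;
    }

  // monotone maximum-accuracy alignment over (k, j)
  std::vector<double> A((size_t)(m + 1) * (L + 1), 0.0);
  std::vector<signed char> tb((size_t)(m + 1) * (L + 1), 0);
  auto AX = [m](int k, int j) { return (size_t)j * (m + 1) + k; };
  for (int k = 1; k <= m; ++k)
    for (int j = 1; j <= L; ++j) {
      double diag = A[AX(k - 1, j - 1)] + PP[IX(k - 1, j)] - delta;
      double up = A[AX(k - 1, j)];
      double left = A[AX(k, j - 1)];
      double best = diag; signed char t = 1;
      if (up > best) { best = up; t = 2; }
      if (left > best) { best = left; t = 3; }
      A[AX(k, j)] = best; tb[AX(k, j)] = t;
    }

  IntegerVector path(L, 0);
  int k = m, j = L;
  while (k > 0 && j > 0) {
    signed char t = tb[AX(k, j)];
    if (t == 1) { path[j - 1] = k; --k; --j; }
    else if (t == 2) { --k; }
    else { --j; }
  }
  // residues between matched neighbours are domain inserts
  int first = -1, last = -1, prevk = 0;
  for (int j2 = 0; j2 < L; ++j2)
    if (path[j2] > 0) { if (first < 0) first = j2; last = j2; }
  for (int j2 = 0; j2 < L; ++j2) {
    if (path[j2] > 0) { prevk = path[j2]; continue; }
    if (first >= 0 && j2 > first && j2 < last) path[j2] = -prevk;
  }
  return path;
}
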