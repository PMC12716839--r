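#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Local (uni-hit) profile-HMM dynamic programming over a digitized sequence.
//
// Model: match states M_1..M_L with emission odds eo[j][a] (model/background),
// insert emissions tied to background (odds 1), delete states silent.
// Entry B -> M_j uniform 1/L; exit M_j -> E with probability 1/(L-j+1),
// the remaining mass scaling the core M transitions so every outgoing group
// stays normalized. The alignment start position carries a uniform 1/n
// prior over the n target residues, and residues outside the aligned core
// emit background and contribute nothing to the log-odds.
//
// tr columns: 0 MM, 1 MI, 2 MD, 3 IM, 4 II, 5 DM, 6 DD (transition out of
// column j toward column j+1). seq codes: 0..19 canonical, 20 = X (odds 1).

static const double SCALE_THRESH = 1e250;

// [[Rcpp::export]]
double hmm_forward_cpp(NumericMatrix eo, NumericMatrix tr, IntegerVector seq) {
  const int L = eo.nrow();
  const int n = seq.size();
  if (n == 0) return R_NegInf;
  std::vector<double> pend(L), aMM(L), aMI(L), aMD(L);
  for (int j = 0; j < L; ++j) {
    pend[j] = 1.0 / (double)(L - j);
    double keep = 1.0 - pend[j];
    aMM[j] = tr(j, 0) * keep;
    aMI[j] = tr(j, 1) * keep;
    aMD[j] = tr(j, 2) * keep;
  }
  const double entry = 1.0 / (double)L;

  std::vector<double> FMprev(L, 0.0), FIprev(L, 0.0), FDprev(L, 0.0);
  std::vector<double> FM(L), FI(L), FD(L);
  double logscale = 0.0;          // cumulative log of applied scalings
  double totLog = R_NegInf;       // log of summed exit mass

  for (int i = 0; i < n; ++i) {
    const int a = seq[i];
    double rowmax = 0.0;
    for (int j = 0; j < L; ++j) {
      const double e = (a >= 20 || a < 0) ? 1.0 : eo(j, a);
      double m = entry;
      if (j > 0) {
        m += FMprev[j - 1] * aMM[j - 1] + FIprev[j - 1] * tr(j - 1, 3) +
             FDprev[j - 1] * tr(j - 1, 5);
      }
      FM[j] = e * m;
      FI[j] = FMprev[j] * aMI[j] + FIprev[j] * tr(j, 4);
      FD[j] = (j > 0) ? (FM[j - 1] * aMD[j - 1] + FD[j - 1] * tr(j - 1, 6))
                      : 0.0;
      if (FM[j] > rowmax) rowmax = FM[j];
      if (FI[j] > rowmax) rowmax = FI[j];
      if (FD[j] > rowmax) rowmax = FD[j];
    }
    // exit mass from this row, in absolute log space
    double rowexit = 0.0;
    for (int j = 0; j < L; ++j) rowexit += FM[j] * pend[j];
    if (rowexit > 0.0) {
      double lc = std::log(rowexit) + logscale;
      if (totLog == R_NegInf) totLog = lc;
      else {
        double hi = totLog > lc ? totLog : lc;
        totLog = hi + std::log1p(std::exp((totLog < lc ? totLog : lc) - hi));
      }
    }
    if (rowmax > SCALE_THRESH) {
      const double s = 1.0 / rowmax;
      for (int j = 0; j < L; ++j) { FM[j] *= s; FI[j] *= s; FD[j] *= s; }
      logscale += std::log(rowmax);
    }
    FMprev.swap(FM); FIprev.swap(FI); FDprev.swap(FD);
  }
  if (totLog == R_NegInf) return R_NegInf;
  return (totLog - std::log((double)n)) / std::log(2.0);
}

// [[Rcpp::export]]
List hmm_viterbi_cpp(NumericMatrix eo, NumericMatrix tr, IntegerVector seq) {
  const int L = eo.nrow();
  const int n = seq.size();
  const double NEG = -1e300;
  std::vector<double> pendl(L), aMM(L), aMI(L), aMD(L);
  for (int j = 0; j < L; ++j) {
    double pe = 1.0 / (double)(L - j);
    pendl[j] = std::log(pe);
    double keep = 1.0 - pe;
    aMM[j] = keep > 0 ? std::log(tr(j, 0) * keep) : NEG;
    aMI[j] = keep > 0 ? std::log(tr(j, 1) * keep) : NEG;
    aMD[j] = keep > 0 ? std::log(tr(j, 2) * keep) : NEG;
  }
  const double entry = std::log(1.0 / (double)L);

  std::vector<double> VMp(L, NEG), VIp(L, NEG), VDp(L, NEG);
  std::vector<double> VM(L), VI(L), VD(L);
  std::vector<int> SMp(L, 0), SIp(L, 0), SDp(L, 0); // 1-based start of best path
  std::vector<int> SM(L), SI(L), SD(L);
  double best = NEG;
  int bestStart = 0, bestEnd = 0;

  for (int i = 0; i < n; ++i) {
    const int a = seq[i];
    for (int j = 0; j < L; ++j) {
      const double e =
          (a >= 20 || a < 0) ? 0.0 : std::log(eo(j, a));
      double m = entry; int ms = i + 1;
      if (j > 0) {
        double c1 = VMp[j - 1] + aMM[j - 1];
        double c2 = VIp[j - 1] + std::log(tr(j - 1, 3));
        double c3 = VDp[j - 1] + std::log(tr(j - 1, 5));
        if (c1 > m) { m = c1; ms = SMp[j - 1]; }
        if (c2 > m) { m = c2; ms = SIp[j - 1]; }
        if (c3 > m) { m = c3; ms = SDp[j - 1]; }
      }
      VM[j] = e + m; SM[j] = ms;
      double i1 = VMp[j] + aMI[j];
      double i2 = VIp[j] + std::log(tr(j, 4));
      if (i1 >= i2) { VI[j] = i1; SI[j] = SMp[j]; }
      else          { VI[j] = i2; SI[j] = SIp[j]; }
      if (j > 0) {
        double d1 = VM[j - 1] + aMD[j - 1];
        double d2 = VD[j - 1] + std::log(tr(j - 1, 6));
        if (d1 >= d2) { VD[j] = d1; SD[j] = SM[j - 1]; }
        else          { VD[j] = d2; SD[j] = SD[j - 1]; }
      } else { VD[j] = NEG; SD[j] = 0; }
      double fin = VM[j] + pendl[j];
      if (fin > best) { best = fin; bestStart = SM[j]; bestEnd = i + 1; }
    }
    VMp.swap(VM); VIp.swap(VI); VDp.swap(VD);
    SMp.swap(SM); SIp.swap(SI); SDp.swap(SD);
  }
  double bits = (best <= NEG / 2)
      ? R_NegInf
      : (best - std::log((double)n)) / std::log(2.0);
  return List::create(_["bits"] = bits, _["start"] = bestStart,
                      _["end"] = bestEnd);
}

// Force-directed graph layout (CLANS-style): attraction along edges
// proportional to weight x distance, uniform pairwise repulsion proportional
// to 1/distance, per-cycle step size with linear cooling. Deterministic for
// a given initial configuration.
// [[Rcpp::export]]
NumericMatrix clans_layout_cpp(NumericMatrix coords, IntegerMatrix edges,
                               NumericVector w, int cycles,
                               double attract, double repulse, double step0) {
  const int n = coords.nrow(), d = coords.ncol(), m = edges.nrow();
  NumericMatrix pos(clone(coords));
  std::vector<double> force(n * d);
  for (int t = 0; t < cycles; ++t) {
    std::fill(force.begin(), force.end(), 0.0);
    // repulsion, all pairs
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        double dist2 = 1e-12;
        for (int k = 0; k < d; ++k) {
          double dx = pos(i, k) - pos(j, k);
          dist2 += dx * dx;
        }
        double dist = std::sqrt(dist2);
        double f = repulse / dist;          // magnitude ~ 1/distance
        for (int k = 0; k < d; ++k) {
          double u = (pos(i, k) - pos(j, k)) / dist;
          force[i * d + k] += f * u;
          force[j * d + k] -= f * u;
        }
      }
    }
    // attraction along edges
    for (int e = 0; e < m; ++e) {
      int i = edges(e, 0), j = edges(e, 1);
      double dist2 = 1e-12;
      for (int k = 0; k < d; ++k) {
        double dx = pos(i, k) - pos(j, k);
        dist2 += dx * dx;
      }
      double dist = std::sqrt(dist2);
      double f = attract * w[e] * dist;     // magnitude ~ weight x distance
      for (int k = 0; k < d; ++k) {
        double u = (pos(j, k) - pos(i, k)) / dist;
        force[i * d + k] += f * u;
        force[j * d + k] -= f * u;
      }
    }
    double step = step0 * (1.0 - (double)t / (double)cycles);
    for (int i = 0; i < n; ++i) {
      // cap displacement so early high-force cycles cannot explode
      double norm2 = 0.0;
      for (int k = 0; k < d; ++k) {
        double f = force[i * d + k];
        norm2 += f * f;
      }
      double norm = std::sqrt(norm2);
      double cap = 0.3;
      double scale = (norm * step > cap) ? cap / norm : step;
      for (int k = 0; k < d; ++k) pos(i, k) += scale * force[i * d + k];
    }
  }
  return pos;
}
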