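#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Multi-codon dynamic program with primer accounting over stretches.
//
// State: S[i][j][k][e] = smallest library size over positions 1..i with j
// primers total, k primers covering position i's stretch, and total error e.
// At a first-in-stretch position the previous stretch's primer count k' is
// minimized over (released) and the new stretch starts at k = j'; elsewhere
// choosing j' codons multiplies the running stretch product, demanding
// k - k/j' additional primers. Layers are built error-outermost so the run
// can stop at the first feasible error level (output-sensitive mode).
//
// sTables : per position, an Lp x (m_i + 1) matrix of minimal sizes by
//           (codon count, error), NA = infeasible
// first   : per position, whether it opens a stretch
// Lsize   : diversity limit on the library size
// stopFirst   : stop at the first feasible error level
// minPossible : smallest achievable library size (full-table stopping rule;
//               <= 0 disables)
// [[Rcpp::export]]
List cpp_dp_multi(List sTables, LogicalVector first, int Lp, int Ls, int LT,
                  double Lsize, bool stopFirst, int eCap, double minPossible) {
  const int n = sTables.size();
  const int J = LT + 1, K = Ls + 1;
  const int layerLen = n * J * K;
  const double inf = R_PosInf;

  std::vector<NumericMatrix> s;
  std::vector<int> m(n);
  for (int i = 0; i < n; ++i) {
    NumericMatrix si = sTables[i];
    s.push_back(si);
    m[i] = si.ncol() - 1;
  }
  auto sval = [&](int i, int jp, int ep) -> double {
    if (jp > Lp || ep > m[i]) return inf;
    double v = s[i](jp - 1, ep);
    return ISNAN(v) ? inf : v;
  };
  auto idx = [&](int i, int j, int k) { return (i * J + j) * K + k; };

  std::vector<std::vector<double>> S;       // S[e][cell]
  std::vector<std::vector<int>> tbJp, tbEp, tbKprev;
  NumericVector minSizeByE(eCap + 1, NA_REAL);
  std::vector<int> argJ(eCap + 1, -1), argK(eCap + 1, -1);

  bool feasible = false;
  int optError = -1, explored = -1;

  for (int e = 0; e <= eCap; ++e) {
    S.emplace_back(layerLen, inf);
    tbJp.emplace_back(layerLen, -1);
    tbEp.emplace_back(layerLen, -1);
    tbKprev.emplace_back(layerLen, -1);
    std::vector<double> &Se = S[e];

    for (int i = 0; i < n; ++i) {
      int estar = std::min(e, m[i]);
      if (first[i]) {
        if (i == 0) {
          // whole prefix is this one position: j = k = j', e = e'
          for (int jp = 1; jp <= std::min(Lp, std::min(Ls, LT)); ++jp) {
            double v = sval(0, jp, e);
            if (v < inf) {
              int cell = idx(0, jp, jp);
              Se[cell] = v;
              tbJp[e][cell] = jp; tbEp[e][cell] = e; tbKprev[e][cell] = 0;
            }
          }
        } else {
          for (int jp = 1; jp <= std::min(Lp, Ls); ++jp) {
            for (int j = jp + 1; j <= LT; ++j) {   // jprev = j - jp >= 1
              int cell = idx(i, j, jp);
              int jprev = j - jp;
              for (int ep = 0; ep <= estar; ++ep) {
                double sv = sval(i, jp, ep);
                if (sv >= inf) continue;
                const std::vector<double> &Sp = S[e - ep];
                for (int kp = 1; kp <= Ls; ++kp) {
                  double prev = Sp[idx(i - 1, jprev, kp)];
                  if (prev >= inf) continue;
                  double cand = prev * sv;
                  if (cand < Se[cell]) {
                    Se[cell] = cand;
                    tbJp[e][cell] = jp; tbEp[e][cell] = ep;
                    tbKprev[e][cell] = kp;
                  }
                }
              }
            }
          }
        }
      } else {
        for (int k = 1; k <= Ls; ++k) {
          for (int j = 1; j <= LT; ++j) {
            int cell = idx(i, j, k);
            for (int ep = 0; ep <= estar; ++ep) {
              const std::vector<double> &Sp = S[e - ep];
              for (int jp = 1; jp <= std::min(Lp, k); ++jp) {
                if (k % jp != 0) continue;
                int kprev = k / jp;
                int jprev = j - (k - kprev);
                if (jprev < 1) continue;
                double sv = sval(i, jp, ep);
                if (sv >= inf) continue;
                double prev = Sp[idx(i - 1, jprev, kprev)];
                if (prev >= inf) continue;
                double cand = prev * sv;
                if (cand < Se[cell]) {
                  Se[cell] = cand;
                  tbJp[e][cell] = jp; tbEp[e][cell] = ep;
                  tbKprev[e][cell] = kprev;
                }
              }
            }
          }
        }
      }
    }

    // readout over the final position
    double best = inf;
    for (int j = 1; j <= LT; ++j)
      for (int k = 1; k <= Ls; ++k) {
        double v = Se[idx(n - 1, j, k)];
        if (v < best) { best = v; argJ[e] = j; argK[e] = k; }
      }
    if (best < inf) minSizeByE[e] = best;
    explored = e;
    if (!feasible && best <= Lsize) {
      feasible = true;
      optError = e;
      if (stopFirst) break;
    }
    if (feasible && minPossible > 0 && best <= minPossible) break;
  }

  IntegerMatrix choices(n, 2);
  int optJ = -1, optK = -1;
  if (feasible) {
    int e = optError, j = argJ[optError], k = argK[optError];
    optJ = j; optK = k;
    for (int i = n - 1; i >= 0; --i) {
      int cell = idx(i, j, k);
      int jp = tbJp[e][cell], ep = tbEp[e][cell], kprev = tbKprev[e][cell];
      if (jp < 0) stop("traceback hit an unset cell (internal error)");
      choices(i, 0) = jp;
      choices(i, 1) = (i == 0) ? e : ep;
      if (i > 0) {
        if (first[i]) { j = j - jp; k = kprev; }
        else         { j = j - (k - k / jp); k = k / jp; }
        e -= ep;
      }
    }
  }

  return List::create(
      _["feasible"] = feasible, _["optError"] = optError, _["optJ"] = optJ,
      _["optK"] = optK, _["explored"] = explored,
      _["minSizeByE"] = minSizeByE[Range(0, std::max(explored, 0))],
      _["choices"] = choices);
}
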