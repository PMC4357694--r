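#include <Rcpp.h>
#include <functional>
#include <vector>
using namespace Rcpp;

// Enumerate unordered sets of 2..Lp distinct candidate codons and record, per
// (set size, union error), the minimal combined DNA size with one witness.
// Candidates arrive sorted in the canonical lexicographic codon order, so the
// first strict improvement encountered is the lexicographically smallest
// witness among minimal-size sets.
//
// aaMask  : 21-bit amino-acid coverage mask per candidate
// deg     : degeneracy per candidate
// baseErr : sum of the position's counts
// delta   : per-symbol penalty-minus-count (length 21); union error =
//           baseErr + sum of delta over covered symbols
// reqMask : required-symbol mask the union must cover
// [[Rcpp::export]]
List cpp_enum_sets(IntegerVector aaMask, NumericVector deg, double baseErr,
                   NumericVector delta, int reqMask, int Lp) {
  const int n = aaMask.size();
  std::vector<int> relBits;
  for (int b = 0; b < 21; ++b)
    if (delta[b] != 0.0) relBits.push_back(b);

  double eMax = baseErr;
  for (int b : relBits)
    if (delta[b] > 0) eMax += delta[b];
  const int E = (int)eMax;

  // byte-indexed partial sums of delta so the error contribution of newly
  // covered symbols costs three table lookups instead of a bit loop
  std::vector<double> W0(256, 0.0), W1(256, 0.0), W2(256, 0.0);
  for (int v = 0; v < 256; ++v)
    for (int b = 0; b < 8; ++b)
      if (v & (1 << b)) {
        W0[v] += delta[b];
        if (b + 8 < 21) W1[v] += delta[b + 8];
        if (b + 16 < 21) W2[v] += delta[b + 16];
      }
  auto deltaSum = [&](int mask) {
    return W0[mask & 255] + W1[(mask >> 8) & 255] + W2[(mask >> 16) & 255];
  };

  const double inf = R_PosInf;
  // best[j-2][e] and witness index tuples per depth
  std::vector<std::vector<double>> best(Lp - 1,
                                        std::vector<double>(E + 1, inf));
  std::vector<std::vector<std::vector<int>>> wit(
      Lp - 1, std::vector<std::vector<int>>(E + 1));

  std::vector<int> stack(Lp);
  std::vector<int> unionMask(Lp + 1, 0);
  std::vector<double> sizeSum(Lp + 1, 0.0);
  std::vector<double> errAt(Lp + 1, baseErr);

  // depth-first enumeration in lexicographic index order
  std::function<void(int, int)> rec = [&](int depth, int start) {
    for (int c = start; c < n; ++c) {
      int u = unionMask[depth] | aaMask[c];
      double err = errAt[depth];
      int added = aaMask[c] & ~unionMask[depth];
      if (added) err += deltaSum(added);
      stack[depth] = c;
      int d = depth + 1;  // current set size
      unionMask[d] = u;
      sizeSum[d] = sizeSum[depth] + deg[c];
      errAt[d] = err;
      if (d >= 2 && (u & reqMask) == reqMask) {
        int e = (int)err;
        if (sizeSum[d] < best[d - 2][e]) {
          best[d - 2][e] = sizeSum[d];
          wit[d - 2][e].assign(stack.begin(), stack.begin() + d);
        }
      }
      if (d < Lp) rec(d, c + 1);
    }
  };
  rec(0, 0);

  List out(Lp - 1);
  for (int j = 0; j < Lp - 1; ++j) {
    int m = 0;
    for (int e = 0; e <= E; ++e)
      if (best[j][e] < inf) ++m;
    IntegerVector errs(m);
    NumericVector sizes(m);
    List wl(m);
    int k = 0;
    for (int e = 0; e <= E; ++e)
      if (best[j][e] < inf) {
        errs[k] = e;
        sizes[k] = best[j][e];
        IntegerVector w(wit[j][e].size());
        for (int t = 0; t < (int)wit[j][e].size(); ++t)
          w[t] = wit[j][e][t] + 1;  // 1-based for R
        wl[k] = w;
        ++k;
      }
    out[j] = List::create(_["error"] = errs, _["size"] = sizes,
                          _["witness"] = wl);
  }
  return out;
}
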