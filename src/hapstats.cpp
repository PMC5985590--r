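// Compiled kernels for haplotype homozygosity statistics. Matrices are
// haplotypes x sites with 0 = ancestral, 1 = derived.

#include <Rcpp.h>
#include <vector>
#include <map>
using namespace Rcpp;

// EHH among carriers of `allele` at `core` (0-based column), evaluated at
// every site: entry j is the probability that two random carriers are
// identical over all sites between the core and j (inclusive). Entry at the
// core itself is 1 by definition.
// [[Rcpp::export]]
NumericVector ehh_curve_cpp(IntegerMatrix H, int core, int allele) {
  int n = H.nrow(), S = H.ncol();
  std::vector<int> car;
  for (int i = 0; i < n; ++i) if (H(i, core) == allele) car.push_back(i);
  int nc = (int) car.size();
  NumericVector out(S, NA_REAL);
  if (nc < 2) return out;
  double denom = nc * (nc - 1) / 2.0;
  out[core] = 1.0;
  for (int dir = -1; dir <= 1; dir += 2) {
    std::vector<int> grp(nc, 0);
    int ngrp = 1;
    for (int j = core + dir; j >= 0 && j < S; j += dir) {
      std::map<std::pair<int, int>, int> key;
      for (int c = 0; c < nc; ++c) {
        auto k = std::make_pair(grp[c], H(car[c], j));
        auto it = key.find(k);
        if (it == key.end()) { key[k] = (int) key.size(); }
        grp[c] = key[k];
      }
      ngrp = (int) key.size();
      std::vector<int> sz(ngrp, 0);
      for (int c = 0; c < nc; ++c) ++sz[grp[c]];
      double hom = 0.0;
      for (int g = 0; g < ngrp; ++g) hom += sz[g] * (sz[g] - 1) / 2.0;
      out[j] = hom / denom;
      if (hom == 0.0) {  // fully refined; stays 0 outward
        for (int jj = j + dir; jj >= 0 && jj < S; jj += dir) out[jj] = 0.0;
        break;
      }
    }
  }
  return out;
}

// Mean over carrier pairs of the number of consecutive sites (including the
// core) across which the pair is identical -- the haplotype-length measure of
// the nSL statistic. Runs are bounded by the region edges.
// [[Rcpp::export]]
double nsl_mean_length_cpp(IntegerMatrix H, int core, int allele) {
  int n = H.nrow(), S = H.ncol();
  std::vector<int> car;
  for (int i = 0; i < n; ++i) if (H(i, core) == allele) car.push_back(i);
  int nc = (int) car.size();
  if (nc < 2) return NA_REAL;
  double tot = 0.0;
  long np = 0;
  for (int a = 0; a < nc; ++a)
    for (int b = a + 1; b < nc; ++b) {
      int i = car[a], j = car[b];
      int lo = core, hi = core;
      while (lo - 1 >= 0 && H(i, lo - 1) == H(j, lo - 1)) --lo;
      while (hi + 1 < S && H(i, hi + 1) == H(j, hi + 1)) ++hi;
      tot += hi - lo + 1;
      ++np;
    }
  return tot / np;
}

// Per-site contribution to pairwise nucleotide diversity:
// 2 * k * (n - k) / (n * (n - 1)) for derived count k.
// [[Rcpp::export]]
NumericVector site_pi_cpp(IntegerMatrix H) {
  int n = H.nrow(), S = H.ncol();
  NumericVector out(S);
  double denom = n * (n - 1.0);
  for (int j = 0; j < S; ++j) {
    double k = 0;
    for (int i = 0; i < n; ++i) if (H(i, j) == 1) ++k;
    out[j] = 2.0 * k * (n - k) / denom;
  }
  return out;
}
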