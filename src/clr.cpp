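// Sweep composite-likelihood-ratio kernel. The background site-frequency
// spectrum (classes 1..n of derived counts, optionally including the
// fixed-derived class n) is distorted by a sweep through independent lineage
// escape: at distance d from the selected site each of the n lineages escapes
// the sweep with probability 1 - exp(-alpha * d); non-escaped lineages
// coalesce into a single ancestor at the sweep's end. The likelihood of the
// observed frequency classes is contrasted against the undistorted background.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

// downsampling table: D[m][i] = P(i derived among m of the n lineages)
static std::vector<std::vector<double>> downsample_table(const std::vector<double>& q, int n) {
  std::vector<std::vector<double>> D(n + 1);
  D[n].assign(n + 1, 0.0);
  for (int j = 1; j <= n; ++j) D[n][j] = q[j - 1];
  for (int m = n - 1; m >= 1; --m) {
    D[m].assign(m + 1, 0.0);
    for (int i = 0; i <= m; ++i) {
      D[m][i] = D[m + 1][i] * (double)(m + 1 - i) / (m + 1);
      D[m][i] += D[m + 1][i + 1] * (double)(i + 1) / (m + 1);
    }
  }
  return D;
}

// sweep-transformed spectrum over observable classes for escape prob pe
static std::vector<double> sweep_transform(const std::vector<std::vector<double>>& D,
                                           int n, double pe, bool fixed_class) {
  std::vector<double> p(n + 1, 0.0);  // classes 0..n
  for (int B = 0; B <= n; ++B) {
    double wB = R::dbinom(B, n, pe, 0);
    if (wB <= 0.0) continue;
    if (B == n) {
      for (int j = 1; j <= n; ++j) p[j] += wB * D[n][j];
    } else {
      int m = B + 1;
      for (int i = 0; i <= m; ++i) {
        double di = D[m][i];
        if (di <= 0.0) continue;
        double pm = (double) i / m;               // merged lineage derived
        if (i >= 1) p[i - 1 + (n - B)] += wB * di * pm;
        p[i] += wB * di * (1.0 - pm);
      }
    }
  }
  // renormalize over observable classes
  int jmax = fixed_class ? n : n - 1;
  double tot = 0.0;
  for (int j = 1; j <= jmax; ++j) tot += p[j];
  std::vector<double> out(n, 0.0);
  for (int j = 1; j <= jmax; ++j) out[j - 1] = p[j] / tot;
  return out;
}

// [[Rcpp::export]]
List clr_scan_cpp(IntegerVector counts, NumericVector pos, int n,
                  NumericVector q, NumericVector grid, NumericVector alphas,
                  bool exact, double ycut, int ntab) {
  int S = counts.size(), G = grid.size(), A = alphas.size();
  bool fixed_class = q[n - 1] > 0.0;
  std::vector<double> qq(q.begin(), q.end());
  double qtot = 0.0;
  for (double v : qq) qtot += v;
  for (double& v : qq) v /= qtot;
  auto D = downsample_table(qq, n);

  std::vector<double> lnq(n, -1e12);
  for (int j = 0; j < n; ++j) if (qq[j] > 0.0) lnq[j] = std::log(qq[j]);

  // interpolation table in y = alpha * d: row 0 is y = 0, the rest log-spaced
  std::vector<double> ys;
  std::vector<std::vector<double>> tab;
  double ylo = 1e-6;
  if (!exact) {
    ys.push_back(0.0);
    tab.push_back(sweep_transform(D, n, 0.0, fixed_class));
    for (int t = 0; t < ntab; ++t) {
      double y = ylo * std::pow(ycut / ylo, (double) t / (ntab - 1));
      ys.push_back(y);
      tab.push_back(sweep_transform(D, n, 1.0 - std::exp(-y), fixed_class));
    }
    for (auto& row : tab)
      for (double& v : row) v = (v > 0.0) ? std::log(v) : -1e12;
  }
  double lstep = std::log(ycut / ylo) / (ntab - 1);

  NumericVector clr(G), ahat(G);
  for (int g = 0; g < G; ++g) {
    double best = 0.0, besta = NA_REAL;
    for (int a = 0; a < A; ++a) {
      double alpha = alphas[a];
      double dcut = ycut / alpha;
      int lo = (int) (std::lower_bound(pos.begin(), pos.end(), grid[g] - dcut) - pos.begin());
      int hi = (int) (std::upper_bound(pos.begin(), pos.end(), grid[g] + dcut) - pos.begin());
      double lam = 0.0;
      if (exact) {
        for (int s = lo; s < hi; ++s) {
          double y = alpha * std::fabs(pos[s] - grid[g]);
          auto pv = sweep_transform(D, n, 1.0 - std::exp(-y), fixed_class);
          double v = pv[counts[s] - 1];
          lam += ((v > 0.0) ? std::log(v) : -1e12) - lnq[counts[s] - 1];
        }
      } else {
        for (int s = lo; s < hi; ++s) {
          double y = alpha * std::fabs(pos[s] - grid[g]);
          double lp;
          int j = counts[s] - 1;
          if (y >= ycut) continue;
          if (y <= 0.0) lp = tab[0][j];
          else if (y < ylo) {
            double w = y / ylo;
            lp = (1.0 - w) * tab[0][j] + w * tab[1][j];
          } else {
            double f = std::log(y / ylo) / lstep;
            int t = (int) f;
            if (t >= ntab - 1) { t = ntab - 2; f = (double) t + 1.0; }
            double w = f - t;
            lp = (1.0 - w) * tab[t + 1][j] + w * tab[t + 2][j];
          }
          lam += lp - lnq[j];
        }
      }
      if (lam > best) { best = lam; besta = alpha; }
    }
    clr[g] = 2.0 * best;
    ahat[g] = besta;
  }
  return List::create(_["clr"] = clr, _["alpha_hat"] = ahat);
}

// exposed for the nesting/oracle tests
// [[Rcpp::export]]
NumericVector sweep_transform_cpp(NumericVector q, int n, double y) {
  bool fixed_class = q[n - 1] > 0.0;
  std::vector<double> qq(q.begin(), q.end());
  double qtot = 0.0;
  for (double v : qq) qtot += v;
  for (double& v : qq) v /= qtot;
  auto D = downsample_table(qq, n);
  auto p = sweep_transform(D, n, 1.0 - std::exp(-y), fixed_class);
  return NumericVector(p.begin(), p.end());
}
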