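// Structured-coalescent machinery shared by the neutral and selective-sweep
// simulators. Lineages carry lists of ancestral segments, each tagged with the
// set of sampled haplotypes descending from it; mutations dropped on a segment
// are therefore resolved to sample rows without storing marginal trees.
// Time is measured in generations throughout; the sweep phase runs in discrete
// generations along a supplied allele-frequency trajectory (Hudson-style
// per-generation rates), the neutral phases in continuous time.

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cstdint>
using namespace Rcpp;

typedef std::vector<uint64_t> Mask;

struct Seg {
  double l, r;  // half-open [l, r)
  Mask m;       // descendant sample set
};

struct Mut {
  double pos;
  Mask m;
};

struct Lin {
  std::vector<Seg> segs;  // sorted, disjoint, unfixed material only
  int cls;                // 1 = linked to beneficial allele, 0 = background
  double sl, sr;          // span endpoints
  double ul;              // total unfixed material length
  void refresh() {
    if (segs.empty()) { sl = sr = ul = 0.0; return; }
    sl = segs.front().l;
    sr = segs.back().r;
    ul = 0.0;
    for (const Seg& s : segs) ul += s.r - s.l;
  }
};

static inline bool mask_eq(const Mask& a, const Mask& b) {
  for (size_t i = 0; i < a.size(); ++i) if (a[i] != b[i]) return false;
  return true;
}

struct Sim {
  int n, nw;
  Mask full;
  double N, mu_bp, r_bp, L, sweep_pos;
  std::vector<Lin> lins;
  std::vector<Mut> muts;
  double tot_span, tot_ul;
  int kd, ka;

  void recount() {
    tot_span = tot_ul = 0.0;
    kd = ka = 0;
    for (const Lin& l : lins) {
      tot_span += l.sr - l.sl;
      tot_ul += l.ul;
      if (l.cls == 1) ++kd; else ++ka;
    }
  }

  bool done() const { return tot_ul <= 1e-12; }

  void drop_empty() {
    size_t j = 0;
    for (size_t i = 0; i < lins.size(); ++i)
      if (!lins[i].segs.empty()) {
        if (j != i) lins[j] = std::move(lins[i]);
        ++j;
      }
    lins.resize(j);
  }

  // merge segment lists of two lineages; full (fixed) pieces are discarded
  std::vector<Seg> merge_segs(const std::vector<Seg>& A, const std::vector<Seg>& B) {
    std::vector<double> cuts;
    cuts.reserve(2 * (A.size() + B.size()));
    for (const Seg& s : A) { cuts.push_back(s.l); cuts.push_back(s.r); }
    for (const Seg& s : B) { cuts.push_back(s.l); cuts.push_back(s.r); }
    std::sort(cuts.begin(), cuts.end());
    cuts.erase(std::unique(cuts.begin(), cuts.end()), cuts.end());
    std::vector<Seg> out;
    size_t ia = 0, ib = 0;
    for (size_t c = 0; c + 1 < cuts.size(); ++c) {
      double lo = cuts[c], hi = cuts[c + 1];
      double mid = 0.5 * (lo + hi);
      while (ia < A.size() && A[ia].r <= mid) ++ia;
      while (ib < B.size() && B[ib].r <= mid) ++ib;
      bool ina = ia < A.size() && A[ia].l <= mid;
      bool inb = ib < B.size() && B[ib].l <= mid;
      if (!ina && !inb) continue;
      Mask m(nw, 0);
      if (ina) for (int w = 0; w < nw; ++w) m[w] |= A[ia].m[w];
      if (inb) for (int w = 0; w < nw; ++w) m[w] |= B[ib].m[w];
      if (mask_eq(m, full)) continue;  // reached its MRCA: fixed in sample
      if (!out.empty() && out.back().r == lo && mask_eq(out.back().m, m))
        out.back().r = hi;
      else
        out.push_back(Seg{lo, hi, std::move(m)});
    }
    return out;
  }

  void coalesce(size_t i, size_t j) {
    Lin merged;
    merged.cls = lins[i].cls;
    merged.segs = merge_segs(lins[i].segs, lins[j].segs);
    merged.refresh();
    if (j < i) std::swap(i, j);
    lins.erase(lins.begin() + j);
    lins.erase(lins.begin() + i);
    if (!merged.segs.empty()) lins.push_back(std::move(merged));
    recount();
  }

  // split lineage idx at breakpoint b; returns index of the unlinked half
  // (the side not containing sweep_pos); caller decides its class
  size_t recombine(size_t idx, double b) {
    Lin left, right;
    left.cls = right.cls = lins[idx].cls;
    for (const Seg& s : lins[idx].segs) {
      if (s.r <= b) left.segs.push_back(s);
      else if (s.l >= b) right.segs.push_back(s);
      else {
        left.segs.push_back(Seg{s.l, b, s.m});
        right.segs.push_back(Seg{b, s.r, s.m});
      }
    }
    left.refresh(); right.refresh();
    bool left_linked = sweep_pos < b;
    lins[idx] = left_linked ? std::move(left) : std::move(right);
    lins.push_back(left_linked ? std::move(right) : std::move(left));
    recount();
    return lins.size() - 1;
  }

  size_t pick_by_span(double u) {
    double acc = 0.0;
    for (size_t i = 0; i < lins.size(); ++i) {
      acc += lins[i].sr - lins[i].sl;
      if (u <= acc) return i;
    }
    return lins.size() - 1;
  }

  size_t pick_in_class(int cls, int which) {
    int c = 0;
    for (size_t i = 0; i < lins.size(); ++i)
      if (lins[i].cls == cls && c++ == which) return i;
    return 0;  // unreachable for valid input
  }

  void mutate(double dt) {
    if (dt <= 0.0 || tot_ul <= 0.0 || mu_bp <= 0.0) return;
    double lambda = mu_bp * tot_ul * dt;
    int cnt = (int) R::rpois(lambda);
    for (int c = 0; c < cnt; ++c) {
      double u = unif_rand() * tot_ul;
      double acc = 0.0;
      for (const Lin& l : lins) {
        if (u > acc + l.ul) { acc += l.ul; continue; }
        double v = u - acc;
        for (const Seg& s : l.segs) {
          double w = s.r - s.l;
          if (v > w) { v -= w; continue; }
          muts.push_back(Mut{s.l + v, s.m});
          break;
        }
        break;
      }
    }
  }

  // continuous-time neutral phase; returns true if all material fixed
  bool neutral_phase(double tmax) {
    double t = 0.0;
    while (true) {
      if (done()) return true;
      int k = (int) lins.size();
      double Rc = k * (k - 1) / 2.0 / (2.0 * N);
      double Rr = r_bp * tot_span;
      double R = Rc + Rr;
      if (R <= 0.0) return true;
      double w = R::rexp(1.0 / R);
      if (t + w >= tmax) { mutate(tmax - t); return false; }
      mutate(w);
      t += w;
      if (unif_rand() * R < Rc) {
        int i = (int) (unif_rand() * k);
        int j = (int) (unif_rand() * (k - 1));
        if (j >= i) ++j;
        coalesce(i, j);
      } else {
        size_t idx = pick_by_span(unif_rand() * tot_span);
        double b = lins[idx].sl + unif_rand() * (lins[idx].sr - lins[idx].sl);
        recombine(idx, b);
      }
      drop_empty();
      recount();
    }
  }

  // discrete-generation structured phase along the (backward) trajectory
  void sweep_phase(const NumericVector& traj) {
    for (R_xlen_t g = 1; g < traj.size(); ++g) {
      double x = traj[g];
      if (x <= 0.0) break;
      if (done()) return;
      double tgen = 0.0;
      while (true) {
        double Rcd = (kd >= 2 && x > 0.0) ? kd * (kd - 1) / 2.0 / (2.0 * N * x) : 0.0;
        double Rca = (ka >= 2 && x < 1.0) ? ka * (ka - 1) / 2.0 / (2.0 * N * (1.0 - x)) : 0.0;
        double Rr = r_bp * tot_span;
        double R = Rcd + Rca + Rr;
        if (R <= 0.0) { mutate(1.0 - tgen); break; }
        double w = R::rexp(1.0 / R);
        if (tgen + w >= 1.0) { mutate(1.0 - tgen); break; }
        mutate(w);
        tgen += w;
        double u = unif_rand() * R;
        if (u < Rcd || (u < Rcd + Rca)) {
          int cls = (u < Rcd) ? 1 : 0;
          int kc = (cls == 1) ? kd : ka;
          int a = (int) (unif_rand() * kc);
          int b = (int) (unif_rand() * (kc - 1));
          if (b >= a) ++b;
          coalesce(pick_in_class(cls, a), pick_in_class(cls, b));
        } else {
          size_t idx = pick_by_span(unif_rand() * tot_span);
          double b = lins[idx].sl + unif_rand() * (lins[idx].sr - lins[idx].sl);
          size_t un = recombine(idx, b);
          lins[un].cls = (unif_rand() < x) ? 1 : 0;
          recount();
        }
        drop_empty();
        recount();
        if (done()) return;
      }
    }
    // trajectory exhausted: remaining beneficial-class lineages descend from
    // the mutation's origin and coalesce there; survivor joins the background
    while (kd >= 2) {
      coalesce(pick_in_class(1, 0), pick_in_class(1, 1));
      drop_empty();
      recount();
    }
    for (Lin& l : lins) l.cls = 0;
    recount();
  }
};

static Sim make_sim(int n_hap, double N, double mu_bp, double r_bp, double L,
                    double sweep_pos, int start_cls) {
  Sim S;
  S.n = n_hap;
  S.nw = (n_hap + 63) / 64;
  S.full.assign(S.nw, 0);
  for (int i = 0; i < n_hap; ++i) S.full[i / 64] |= (uint64_t(1) << (i % 64));
  S.N = N; S.mu_bp = mu_bp; S.r_bp = r_bp; S.L = L; S.sweep_pos = sweep_pos;
  for (int i = 0; i < n_hap; ++i) {
    Lin l;
    Mask m(S.nw, 0);
    m[i / 64] |= (uint64_t(1) << (i % 64));
    l.segs.push_back(Seg{0.0, L, m});
    l.cls = start_cls;
    l.refresh();
    S.lins.push_back(std::move(l));
  }
  S.recount();
  return S;
}

static List collect(Sim& S) {
  std::sort(S.muts.begin(), S.muts.end(),
            [](const Mut& a, const Mut& b) { return a.pos < b.pos; });
  int m = (int) S.muts.size();
  NumericVector pos(m);
  IntegerMatrix H(S.n, m);
  for (int j = 0; j < m; ++j) {
    pos[j] = S.muts[j].pos;
    for (int i = 0; i < S.n; ++i)
      H(i, j) = (S.muts[j].m[i / 64] >> (i % 64)) & 1 ? 1 : 0;
  }
  return List::create(_["positions"] = pos, _["haplotypes"] = H);
}

// [[Rcpp::export]]
List arg_neutral_cpp(int n_hap, double N, double mu_bp, double r_bp, double L) {
  Sim S = make_sim(n_hap, N, mu_bp, r_bp, L, -1.0, 0);
  S.neutral_phase(R_PosInf);
  return collect(S);
}

// [[Rcpp::export]]
List arg_sweep_cpp(int n_hap, double N, double mu_bp, double r_bp, double L,
                   double sweep_pos, NumericVector traj, double t_fix_gens) {
  Sim S = make_sim(n_hap, N, mu_bp, r_bp, L, sweep_pos, 1);
  bool fixed = false;
  if (t_fix_gens > 0.0) fixed = S.neutral_phase(t_fix_gens);
  if (!fixed) {
    S.sweep_phase(traj);
    S.neutral_phase(R_PosInf);
  }
  return collect(S);
}

// Forward Wright-Fisher trajectory of a beneficial allele, conditioned on
// fixation by rejection. Genotype fitnesses 1, 1 + s/2, 1 + s. Returns the
// frequency path reversed in time: 1 (fixation), ..., 1/(2N), 0.
// [[Rcpp::export]]
List wf_trajectory_cpp(double N, double s, int max_attempts) {
  double twoN = 2.0 * N;
  std::vector<double> path;
  int attempts = 0;
  while (attempts < max_attempts) {
    ++attempts;
    path.clear();
    double i = 1.0;
    path.push_back(i / twoN);
    bool fixed = false, lost = false;
    while (!fixed && !lost) {
      double x = i / twoN;
      double wA = x * (1.0 + s) + (1.0 - x) * (1.0 + 0.5 * s);
      double wa = x * (1.0 + 0.5 * s) + (1.0 - x);
      double p = x * wA / (x * wA + (1.0 - x) * wa);
      i = R::rbinom(twoN, p);
      if (i <= 0.0) lost = true;
      else {
        path.push_back(i / twoN);
        if (i >= twoN) fixed = true;
      }
    }
    if (fixed) {
      std::reverse(path.begin(), path.end());
      path.push_back(0.0);
      return List::create(_["freqs"] = NumericVector(path.begin(), path.end()),
                          _["attempts"] = attempts);
    }
  }
  return List::create(_["freqs"] = R_NilValue, _["attempts"] = attempts);
}
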