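// Divergent selection at a single biallelic locus linked to a neutral
// region.  Forward Wright-Fisher trajectories of the selected allele in the
// two demes (mirror-image fitnesses, allele A favored in deme 0), then
// genealogies of the neutral region drawn from the structured coalescent
// conditioned on the trajectory: lineages carry (deme, background) state,
// switch background by recombination between the selected locus and the
// window, migrate with background-frequency weighting, and coalesce within
// (deme, background) classes at rate 1/(2N x).  Genealogies are drawn per
// non-overlapping window (one tree per window; a single tree for the whole
// region when rec = 0); see the methods vignette for what this does and
// does not model.

#include "tree.h"
#include "jc.h"
#include <cmath>

using namespace Rcpp;

namespace {

// post-selection frequency of allele A given its pre-selection frequency x;
// deme 0 favors A, deme 1 favors a, fitnesses (1+s_hom, 1+s_het, 1)
inline double sel_freq(double x, double s_hom, double s_het, int deme) {
  double p = (deme == 0) ? x : 1.0 - x;
  double num = p * p * (1 + s_hom) + p * (1 - p) * (1 + s_het);
  double den = p * p * (1 + s_hom) + 2 * p * (1 - p) * (1 + s_het) +
               (1 - p) * (1 - p);
  double pstar = (den > 0) ? num / den : p;
  return (deme == 0) ? pstar : 1.0 - pstar;
}

List snapshot(const SegTree &T, double lo, double hi) {
  int M = T.n_nodes();
  IntegerVector par(M);
  NumericVector tim(M);
  for (int i = 0; i < M; ++i) {
    par[i] = T.parent[i] < 0 ? NA_INTEGER : T.parent[i] + 1;
    tim[i] = T.time[i];
  }
  return List::create(_["start_bp"] = lo, _["end_bp"] = hi,
                      _["parent"] = par, _["node_time"] = tim,
                      _["n_tips"] = T.n);
}

} // namespace

// Forward two-deme Wright-Fisher trajectory of the selected allele.
// Returns a (Tgen+1) x 2 matrix of the frequency of allele A; row index is
// the generation counted backward from the present (row 0 = present, row
// Tgen = divergence).  Backward migration rates m0/m1 are per-lineage rates
// for demes 0/1 (i.e. the immigrant fraction of that deme per generation),
// active while the backward time lies in [epoch_lo, epoch_hi).
// [[Rcpp::export]]
NumericMatrix wf_trajectory_cpp(double Np, int Tgen, double s_hom,
                                double s_het, double m0, double m1,
                                double epoch_lo, double epoch_hi,
                                double x0_init, double x1_init) {
  if (Np < 1) stop("Np must be >= 1");
  NumericMatrix traj(Tgen + 1, 2);
  double x0 = x0_init, x1 = x1_init;
  traj(Tgen, 0) = x0; traj(Tgen, 1) = x1;
  double twoN = std::round(2.0 * Np);
  for (int f = 1; f <= Tgen; ++f) {
    int tb = Tgen - f; // backward time of the offspring generation
    double xs0 = sel_freq(x0, s_hom, s_het, 0);
    double xs1 = sel_freq(x1, s_hom, s_het, 1);
    bool active = (tb >= epoch_lo && tb < epoch_hi);
    double mm0 = active ? m0 : 0.0, mm1 = active ? m1 : 0.0;
    double xm0 = (1 - mm0) * xs0 + mm0 * xs1;
    double xm1 = (1 - mm1) * xs1 + mm1 * xs0;
    x0 = R::rbinom(twoN, xm0) / twoN;
    x1 = R::rbinom(twoN, xm1) / twoN;
    traj(tb, 0) = x0; traj(tb, 1) = x1;
  }
  return traj;
}

// Count fixations of an allele starting at frequency x_init in a single
// Wright-Fisher deme (deme-0 fitness scheme).  Used against the Kimura
// diffusion prediction in tests.
// [[Rcpp::export]]
int wf_fix_count_cpp(double Np, double s_hom, double s_het, double x_init,
                     int nrep, int max_gen) {
  double twoN = std::round(2.0 * Np);
  int nfix = 0;
  for (int r = 0; r < nrep; ++r) {
    double x = x_init;
    for (int g = 0; g < max_gen && x > 0.0 && x < 1.0; ++g) {
      double xs = sel_freq(x, s_hom, s_het, 0);
      x = R::rbinom(twoN, xs) / twoN;
    }
    if (x >= 1.0) ++nfix;
  }
  return nfix;
}

// [[Rcpp::export]]
List sim_selected_pair_cpp(int n1, int n2, double Np, int Tgen, double L,
                           int window_bp, double rec, double mu,
                           NumericMatrix traj, double s_hom, double s_het,
                           double m0, double m1, double epoch_lo,
                           double epoch_hi, double locus_offset,
                           bool collect_trees, bool mutate) {
  int n = n1 + n2;
  double twoN = std::round(2.0 * Np);
  if (traj.nrow() != Tgen + 1) stop("trajectory length must be Tgen + 1");

  // post-selection frequencies per backward generation, pinned flags
  std::vector<double> xs0(Tgen + 1), xs1(Tgen + 1);
  std::vector<char> pinned(Tgen + 1), need_gen(Tgen + 1, 0);
  for (int tb = 0; tb <= Tgen; ++tb) {
    xs0[tb] = sel_freq(traj(tb, 0), s_hom, s_het, 0);
    xs1[tb] = sel_freq(traj(tb, 1), s_hom, s_het, 1);
    pinned[tb] = (traj(tb, 0) == 1.0 && traj(tb, 1) == 0.0);
  }
  for (int tb = 0; tb < Tgen; ++tb) {
    bool active = (tb >= epoch_lo && tb < epoch_hi);
    need_gen[tb] = (active || !pinned[tb + 1]) ? 1 : 0;
  }
  std::vector<int> next_need(Tgen + 1);
  next_need[Tgen] = Tgen;
  for (int tb = Tgen - 1; tb >= 0; --tb)
    next_need[tb] = need_gen[tb] ? tb : next_need[tb + 1];

  RawMatrix aln;
  if (mutate) {
    aln = RawMatrix(n, (int)L);
    for (int s = 0; s < (int)L; ++s) {
      Rbyte base = (Rbyte)(R::unif_rand() * 4.0);
      if (base > 3) base = 3;
      for (int h = 0; h < n; ++h) aln(h, s) = base;
    }
  }

  int nwin = (rec > 0.0) ? (int)std::ceil(L / window_bp) : 1;
  std::vector<List> segs;
  int n_forced = 0;

  for (int w = 0; w < nwin; ++w) {
    double wlo = (rec > 0.0) ? (double)w * window_bp : 0.0;
    double whi = (rec > 0.0) ? std::min(L, wlo + window_bp) : L;
    double dist = locus_offset + 0.5 * (wlo + whi);
    double pr = (rec > 0.0) ? rec * dist : 0.0;
    if (pr > 1.0) pr = 1.0;

    SegTree T;
    T.init(n);
    std::vector<int> act(n), dem(n), bg(n);
    int foreign = 0;
    for (int i = 0; i < n; ++i) {
      act[i] = i;
      dem[i] = (i < n1) ? 0 : 1;
      double xA = traj(0, dem[i]);
      bg[i] = (R::unif_rand() < xA) ? 0 : 1;
      if (bg[i] != dem[i]) ++foreign; // favored background equals deme index
      T.deme0[i] = dem[i];
    }
    int nxt = n;
    double t = 0.0;
    int k = n;

    while (k > 1) {
      if (t >= Tgen) {
        // ancestral panmictic deme, backgrounds dropped
        double rate = (double)k * (k - 1) / 2.0 / twoN;
        t += R::exp_rand() / rate;
        int a = (int)(R::unif_rand() * k), b;
        do { b = (int)(R::unif_rand() * k); } while (b == a);
        T.time[nxt] = t; T.c1[nxt] = act[a]; T.c2[nxt] = act[b];
        T.parent[act[a]] = nxt; T.parent[act[b]] = nxt;
        act[a] = nxt;
        act.erase(act.begin() + b); dem.erase(dem.begin() + b);
        bg.erase(bg.begin() + b);
        ++nxt; --k;
        continue;
      }
      int ti = (int)t;
      if (!need_gen[ti] && foreign == 0) {
        // neutral stretch: favored alleles fixed in both demes, no
        // migration; independent Kingman coalescent per deme
        double horizon = next_need[ti];
        int k0 = 0;
        for (int i = 0; i < k; ++i) if (dem[i] == 0) ++k0;
        int k1 = k - k0;
        double c0 = (double)k0 * (k0 - 1) / 2.0 / twoN;
        double c1 = (double)k1 * (k1 - 1) / 2.0 / twoN;
        double tot = c0 + c1;
        if (tot <= 0.0) { t = horizon; continue; }
        double dt = R::exp_rand() / tot;
        if (t + dt >= horizon) { t = horizon; continue; }
        t += dt;
        int d = (R::unif_rand() * tot < c0) ? 0 : 1;
        std::vector<int> idx;
        for (int i = 0; i < k; ++i) if (dem[i] == d) idx.push_back(i);
        int a = (int)(R::unif_rand() * idx.size()), b;
        do { b = (int)(R::unif_rand() * idx.size()); } while (b == a);
        int ia = idx[a], ib = idx[b];
        T.time[nxt] = t; T.c1[nxt] = act[ia]; T.c2[nxt] = act[ib];
        T.parent[act[ia]] = nxt; T.parent[act[ib]] = nxt;
        T.deme0[nxt] = d;
        act[ia] = nxt;
        act.erase(act.begin() + ib); dem.erase(dem.begin() + ib);
        bg.erase(bg.begin() + ib);
        ++nxt; --k;
        continue;
      }
      // one discrete generation ti -> ti + 1
      int p = ti + 1;
      double xsd[2] = {xs0[p], xs1[p]};
      bool active = (ti >= epoch_lo && ti < epoch_hi);
      double mm[2] = {active ? m0 : 0.0, active ? m1 : 0.0};
      double xmA[2];
      xmA[0] = (1 - mm[0]) * xsd[0] + mm[0] * xsd[1];
      xmA[1] = (1 - mm[1]) * xsd[1] + mm[1] * xsd[0];
      for (int i = 0; i < k; ++i) {
        int d = dem[i], b = bg[i];
        int src = 1 - d;
        double f_here = (b == 0) ? xsd[d] : 1.0 - xsd[d];
        double f_src  = (b == 0) ? xsd[src] : 1.0 - xsd[src];
        double fmix = (1 - mm[d]) * f_here + mm[d] * f_src;
        if (fmix <= 0.0) {
          ++n_forced;
          if (mm[d] > 0.0 && f_src > 0.0) {
            d = src;
          } else {
            b = (R::unif_rand() < xmA[d]) ? 0 : 1;
          }
        } else if (mm[d] > 0.0) {
          double pm = mm[d] * f_src / fmix;
          if (R::unif_rand() < pm) d = src;
        }
        if (pr > 0.0 && R::unif_rand() < pr) {
          b = (R::unif_rand() < xmA[d]) ? 0 : 1;
        }
        if (dem[i] != d || bg[i] != b) {
          foreign += ((b != d) ? 1 : 0) - ((bg[i] != dem[i]) ? 1 : 0);
          dem[i] = d; bg[i] = b;
        }
      }
      // coalescence within (deme, background) classes
      for (int d = 0; d < 2 && k > 1; ++d) {
        for (int b = 0; b < 2 && k > 1; ++b) {
          std::vector<int> idx;
          for (int i = 0; i < k; ++i)
            if (dem[i] == d && bg[i] == b) idx.push_back(i);
          int c = (int)idx.size();
          if (c < 2) continue;
          double f = (b == 0) ? xmA[d] : 1.0 - xmA[d];
          if (f < 1.0 / twoN) f = 1.0 / twoN;
          if (f > 1.0) f = 1.0;
          double pco = (double)c * (c - 1) / 2.0 / (twoN * f);
          if (pco > 1.0) pco = 1.0;
          if (R::unif_rand() < pco) {
            int a = (int)(R::unif_rand() * c), bb;
            do { bb = (int)(R::unif_rand() * c); } while (bb == a);
            int ia = idx[a], ib = idx[bb];
            T.time[nxt] = ti + 1.0;
            T.c1[nxt] = act[ia]; T.c2[nxt] = act[ib];
            T.parent[act[ia]] = nxt; T.parent[act[ib]] = nxt;
            T.deme0[nxt] = d;
            act[ia] = nxt;
            if (bg[ib] != dem[ib]) --foreign;
            act.erase(act.begin() + ib); dem.erase(dem.begin() + ib);
            bg.erase(bg.begin() + ib);
            ++nxt; --k;
          }
        }
      }
      t = ti + 1.0;
    }
    T.root = nxt - 1;
    if (mutate) jcmut::mutate_segment(T, wlo, whi, mu, aln);
    if (collect_trees) segs.push_back(snapshot(T, wlo, whi));
  }

  List out = List::create(_["n_windows"] = nwin, _["n_forced"] = n_forced);
  if (mutate) out["aln"] = aln;
  if (collect_trees) {
    List sl(segs.size());
    for (size_t i = 0; i < segs.size(); ++i) sl[i] = segs[i];
    out["segments"] = sl;
  }
  return out;
}
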