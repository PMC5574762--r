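// Two-deme structured coalescent with epoch-limited migration and
// recombination along the sequence under the SMC' approximation.
//
// Model: two sister species (demes 0 and 1), each of constant diploid size
// N, splitting from a single ancestral deme (also size N) Tsplit
// generations ago.  Backward in time, lineages coalesce within demes at
// rate 1/(2N) per pair, and migrate deme d -> other at per-lineage rate
// m[d] only while inside the migration epoch [mig_start, mig_end) (times in
// generations before present, epoch clipped to [0, Tsplit)).  Above Tsplit
// all lineages sit in the ancestral deme.
//
// Along the sequence, local trees are updated by SMC': breakpoints arise at
// rate rec * (total branch length) per site; at a breakpoint a uniform
// point on the tree detaches and the floating lineage re-coalesces under
// the same structured dynamics (it may rejoin its own branch, which leaves
// the tree unchanged).  All randomness comes from R's RNG.

#include "tree.h"
#include "jc.h"
#include <cmath>

using namespace Rcpp;

namespace {

const double INF = std::numeric_limits<double>::infinity();

struct Params {
  double N, Tsplit;
  double mig_start, mig_end; // generations before present
  double m0, m1;             // backward per-lineage migration rates by deme
};

inline bool in_epoch(const Params &P, double t) {
  return t >= P.mig_start && t < P.mig_end && t < P.Tsplit;
}

inline double mig_rate(const Params &P, double t, int deme) {
  if (!in_epoch(P, t)) return 0.0;
  return deme == 0 ? P.m0 : P.m1;
}

// next epoch/split boundary strictly above t
inline double next_boundary(const Params &P, double t) {
  double tb = INF;
  const double bs[3] = {P.mig_start, P.mig_end, P.Tsplit};
  for (int i = 0; i < 3; ++i)
    if (bs[i] > t && bs[i] < tb) tb = bs[i];
  return tb;
}

void first_tree(SegTree &T, int n1, int n2, const Params &P) {
  T.init(n1 + n2);
  int ntot = n1 + n2;
  std::vector<int> act(ntot);
  std::vector<int> dem(ntot);
  for (int i = 0; i < ntot; ++i) { act[i] = i; dem[i] = (i < n1) ? 0 : 1; }
  for (int i = 0; i < ntot; ++i) T.deme0[i] = dem[i];
  int nxt = ntot;
  double t = 0.0;
  double twoN = 2.0 * P.N;
  while ((int)act.size() > 1) {
    int k = (int)act.size();
    bool merged = (t >= P.Tsplit);
    int k0 = 0;
    for (int i = 0; i < k; ++i) if (dem[i] == 0) ++k0;
    int k1 = k - k0;
    double c0 = merged ? (double)k * (k - 1) / 2.0 / twoN
                       : (double)k0 * (k0 - 1) / 2.0 / twoN;
    double c1 = merged ? 0.0 : (double)k1 * (k1 - 1) / 2.0 / twoN;
    double mr0 = merged ? 0.0 : k0 * mig_rate(P, t, 0);
    double mr1 = merged ? 0.0 : k1 * mig_rate(P, t, 1);
    double tot = c0 + c1 + mr0 + mr1;
    double tb = next_boundary(P, t);
    if (tot <= 0.0) { t = tb; continue; }
    double dt = R::exp_rand() / tot;
    if (t + dt >= tb) { t = tb; continue; }
    t += dt;
    double u = R::unif_rand() * tot;
    if (u < c0 + c1) {
      int d = (u < c0) ? 0 : 1; // merged => d == 0 branch, any pair
      std::vector<int> idx;
      for (int i = 0; i < k; ++i)
        if (merged || dem[i] == d) idx.push_back(i);
      int a = (int)(R::unif_rand() * idx.size());
      int b;
      do { b = (int)(R::unif_rand() * idx.size()); } while (b == a);
      int ia = idx[a], ib = idx[b];
      int na = act[ia], nb = act[ib];
      T.time[nxt] = t;
      T.c1[nxt] = na; T.c2[nxt] = nb;
      T.parent[na] = nxt; T.parent[nb] = nxt;
      T.deme0[nxt] = merged ? 0 : d;
      // replace lineage ia by new node, drop ib
      act[ia] = nxt; dem[ia] = merged ? 0 : d;
      act.erase(act.begin() + ib); dem.erase(dem.begin() + ib);
      ++nxt;
    } else {
      u -= c0 + c1;
      int d = (u < mr0) ? 0 : 1;
      std::vector<int> idx;
      for (int i = 0; i < k; ++i) if (dem[i] == d) idx.push_back(i);
      int ia = idx[(int)(R::unif_rand() * idx.size())];
      int nd = 1 - d;
      T.migs[act[ia]].push_back({t, nd});
      dem[ia] = nd;
    }
  }
  T.root = nxt - 1;
}

// SMC' re-coalescence after recombination at (branch b, time tr).
// Returns true if the tree changed.
bool smc_recoalesce(SegTree &T, const Params &P, int b, double tr) {
  double twoN = 2.0 * P.N;
  double t = tr;
  int fd = T.deme_at(b, tr);
  double troot = T.time[T.root];
  int vdeme = -1;                 // deme of virtual above-root lineage
  bool vactive = false;
  std::vector<std::pair<double,int>> fmigs, vmigs;
  int M = T.n_nodes();
  int target = -1; bool virt_target = false; double tnew = 0.0;

  for (;;) {
    if (!vactive && t >= troot) { vactive = true; vdeme = T.deme0[T.root]; }
    bool merged = (t >= P.Tsplit);
    // structural horizon: next node time, next migration switch on an alive
    // branch, epoch/split boundary, root activation
    double ts = INF;
    for (int i = 0; i < M; ++i)
      if (T.time[i] > t && T.time[i] < ts) ts = T.time[i];
    for (int i = 0; i < M; ++i) {
      if (!T.alive_at(i, t)) continue;
      for (const auto &mv : T.migs[i])
        if (mv.first > t) { if (mv.first < ts) ts = mv.first; break; }
    }
    double tb = next_boundary(P, t);
    if (tb < ts) ts = tb;
    // candidates for coalescence
    int nsame = 0;
    for (int i = 0; i < M; ++i)
      if (T.alive_at(i, t) && (merged || T.deme_at(i, t) == fd)) ++nsame;
    bool vcand = vactive && (merged || vdeme == fd);
    if (vcand) ++nsame;
    double crate = nsame / twoN;
    double mf = merged ? 0.0 : mig_rate(P, t, fd);
    double mv = (vactive && !merged) ? mig_rate(P, t, vdeme) : 0.0;
    double tot = crate + mf + mv;
    if (tot <= 0.0) { t = ts; continue; }
    double dt = R::exp_rand() / tot;
    if (t + dt >= ts) { t = ts; continue; }
    t += dt;
    double u = R::unif_rand() * tot;
    if (u < crate) {
      int pick = (int)(R::unif_rand() * nsame);
      int chosen = -1; bool vchosen = false;
      int cnt = 0;
      for (int i = 0; i < M && chosen < 0; ++i) {
        if (T.alive_at(i, t) && (merged || T.deme_at(i, t) == fd)) {
          if (cnt == pick) chosen = i;
          ++cnt;
        }
      }
      if (chosen < 0 && vcand) vchosen = true;
      target = chosen; virt_target = vchosen; tnew = t;
      break;
    } else if (u < crate + mf) {
      fd = 1 - fd;
      fmigs.push_back({t, fd});
    } else {
      vdeme = 1 - vdeme;
      vmigs.push_back({t, vdeme});
    }
  }

  if (!virt_target && target == b) return false; // silent: rejoined own branch

  // ---- SPR surgery ----
  int p = T.parent[b];
  int sib = (T.c1[p] == b) ? T.c2[p] : T.c1[p];
  int g = T.parent[p];
  // splice out p: sib's branch absorbs p's branch (and its deme switches)
  for (const auto &mvv : T.migs[p]) T.migs[sib].push_back(mvv);
  T.migs[p].clear();
  T.parent[sib] = g;
  if (g >= 0) {
    if (T.c1[g] == p) T.c1[g] = sib; else T.c2[g] = sib;
  } else {
    T.root = sib;
  }
  int c;
  if (virt_target) {
    c = T.root;             // attach above the (possibly new) root
    for (const auto &mvv : vmigs) T.migs[c].push_back(mvv);
  } else {
    c = (target == p) ? sib : target;
  }
  int cp = T.parent[c];
  // insert node (reuse id p) at tnew on branch c
  T.time[p] = tnew;
  T.c1[p] = b; T.c2[p] = c;
  T.parent[p] = cp;
  if (cp >= 0) {
    if (T.c1[cp] == c) T.c1[cp] = p; else T.c2[cp] = p;
  } else {
    T.root = p;
  }
  T.parent[c] = p; T.parent[b] = p;
  T.deme0[p] = fd;
  // split c's deme switches at tnew: above goes to p's branch
  {
    std::vector<std::pair<double,int>> below, above;
    for (const auto &mvv : T.migs[c]) {
      if (mvv.first <= tnew) below.push_back(mvv); else above.push_back(mvv);
    }
    T.migs[c] = below;
    T.migs[p] = above;
  }
  // b's branch: history below tr, then the float's own path
  {
    std::vector<std::pair<double,int>> keep;
    for (const auto &mvv : T.migs[b]) if (mvv.first <= tr) keep.push_back(mvv);
    for (const auto &mvv : fmigs) keep.push_back(mvv);
    T.migs[b] = keep;
  }
  return true;
}

void check_tree(const SegTree &T, const char *where) {
  int M = T.n_nodes();
  int nroot = 0;
  std::vector<int> childcount(M, 0);
  for (int i = 0; i < M; ++i) {
    if (!std::isfinite(T.time[i])) stop("non-finite node time (%s)", where);
    if (T.parent[i] < 0) { ++nroot; if (i != T.root) stop("stray root (%s)", where); }
    else {
      if (T.time[T.parent[i]] <= T.time[i] && i >= T.n)
        stop("non-increasing times (%s)", where);
      if (T.time[T.parent[i]] < T.time[i])
        stop("parent below child (%s)", where);
      if (T.c1[T.parent[i]] != i && T.c2[T.parent[i]] != i)
        stop("parent/child mismatch (%s)", where);
    }
    if (i >= T.n) {
      if (T.c1[i] < 0 || T.c2[i] < 0) stop("internal node missing child (%s)", where);
      ++childcount[T.c1[i]]; ++childcount[T.c2[i]];
    }
    for (const auto &mvv : T.migs[i]) {
      if (i == T.root) stop("migration on root branch (%s)", where);
      if (mvv.first < T.time[i] - 1e-9 || mvv.first > T.time[T.parent[i]] + 1e-9)
        stop("migration outside branch (%s)", where);
    }
  }
  if (nroot != 1) stop("root count %d (%s)", nroot, where);
  for (int i = 0; i < M; ++i)
    if (childcount[i] > 1) stop("node with >1 parent (%s)", where);
}

// uniform point on the tree: branch with prob proportional to length
void pick_point(const SegTree &T, int &br, double &tt) {
  int M = T.n_nodes();
  double B = T.total_len();
  double u = R::unif_rand() * B;
  double acc = 0.0;
  br = -1;
  for (int i = 0; i < M; ++i) {
    if (i == T.root) continue;
    acc += T.branch_len(i);
    if (u <= acc) { br = i; break; }
  }
  if (br < 0) { for (int i = M - 1; i >= 0; --i) if (i != T.root) { br = i; break; } }
  tt = T.time[br] + R::unif_rand() * T.branch_len(br);
}

List tree_snapshot(const SegTree &T, double lo, double hi) {
  int M = T.n_nodes();
  IntegerVector par(M);
  NumericVector tim(M);
  for (int i = 0; i < M; ++i) {
    par[i] = T.parent[i] < 0 ? NA_INTEGER : T.parent[i] + 1; // 1-based for R
    tim[i] = T.time[i];
  }
  return List::create(_["start_bp"] = lo, _["end_bp"] = hi,
                      _["parent"] = par, _["node_time"] = tim,
                      _["n_tips"] = T.n);
}

} // namespace

// [[Rcpp::export]]
List sim_pair_cpp(int n1, int n2, double N, double Tsplit, double L,
                  double rec, double mu,
                  double mig_start, double mig_end, double m0, double m1,
                  bool collect_trees, bool mutate, bool validate) {
  if (n1 < 1 || n2 < 0) stop("need at least one sampled lineage per deme");
  if (N <= 0) stop("N must be positive");
  Params P{N, Tsplit, mig_start, mig_end, m0, m1};
  SegTree T;
  first_tree(T, n1, n2, P);
  if (validate) check_tree(T, "first tree");

  RawMatrix aln;
  if (mutate) {
    aln = RawMatrix(n1 + n2, (int)L);
    for (int s = 0; s < (int)L; ++s) {
      Rbyte base = (Rbyte)(R::unif_rand() * 4.0);
      if (base > 3) base = 3;
      for (int h = 0; h < n1 + n2; ++h) aln(h, s) = base;
    }
  }

  std::vector<List> segs;
  int n_recomb = 0, n_silent = 0, n_mut = 0;
  double pos = 0.0, seg_start = 0.0;

  while (pos < L) {
    double B = T.total_len();
    double x = (rec > 0.0 && B > 0.0) ? R::exp_rand() / (rec * B) : INF;
    double end = std::min((double)L, pos + x);
    if (mutate) n_mut += jcmut::mutate_segment(T, pos, end, mu, aln);
    pos = end;
    if (pos >= L) {
      if (collect_trees) segs.push_back(tree_snapshot(T, seg_start, L));
      break;
    }
    int br; double tt;
    pick_point(T, br, tt);
    ++n_recomb;
    bool changed = smc_recoalesce(T, P, br, tt);
    if (validate) check_tree(T, "after SMC' step");
    if (!changed) {
      ++n_silent;
    } else if (collect_trees) {
      segs.push_back(tree_snapshot(T, seg_start, pos));
      seg_start = pos;
    }
  }

  List out = List::create(
    _["n_recomb"] = n_recomb,
    _["n_silent"] = n_silent,
    _["n_segments"] = collect_trees ? (int)segs.size() : NA_INTEGER,
    _["n_mut"] = mutate ? n_mut : NA_INTEGER);
  if (mutate) out["aln"] = aln;
  if (collect_trees) {
    List sl(segs.size());
    for (size_t i = 0; i < segs.size(); ++i) sl[i] = segs[i];
    out["segments"] = sl;
  }
  return out;
}

// Single-locus tree only (no recombination machinery), exposed for tests
// and for the small-sample oracle comparisons.
// [[Rcpp::export]]
List sim_single_tree_cpp(int n1, int n2, double N, double Tsplit,
                         double mig_start, double mig_end,
                         double m0, double m1) {
  Params P{N, Tsplit, mig_start, mig_end, m0, m1};
  SegTree T;
  first_tree(T, n1, n2, P);
  return tree_snapshot(T, 0.0, 1.0);
}

// Evolve JC sequences along externally supplied local trees.  `parents`
// and `times` are per-segment node arrays (1-based parents, NA at root);
// segment s covers [starts[s], ends[s]).
// [[Rcpp::export]]
RawMatrix jc_evolve_cpp(List parents, List times, NumericVector starts,
                        NumericVector ends, int n_tips, double L, double mu) {
  int H = n_tips;
  RawMatrix aln(H, (int)L);
  for (int s = 0; s < (int)L; ++s) {
    Rbyte base = (Rbyte)(R::unif_rand() * 4.0);
    if (base > 3) base = 3;
    for (int h = 0; h < H; ++h) aln(h, s) = base;
  }
  for (int k = 0; k < parents.size(); ++k) {
    IntegerVector par = parents[k];
    NumericVector tim = times[k];
    int M = par.size();
    SegTree T;
    T.n = n_tips;
    T.parent.assign(M, -1); T.c1.assign(M, -1); T.c2.assign(M, -1);
    T.time.assign(M, 0.0); T.deme0.assign(M, 0); T.migs.assign(M, {});
    for (int i = 0; i < M; ++i) {
      T.time[i] = tim[i];
      if (par[i] == NA_INTEGER) { T.root = i; continue; }
      int p = par[i] - 1;
      T.parent[i] = p;
      if (T.c1[p] < 0) T.c1[p] = i; else T.c2[p] = i;
      if (tim[i] > tim[p])
        stop("negative branch length in segment %d", k + 1);
    }
    jcmut::mutate_segment(T, starts[k], ends[k], mu, aln);
  }
  return aln;
}
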