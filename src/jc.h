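#ifndef DIVERGOME_JC_H
#define DIVERGOME_JC_H

#include "tree.h"

// Finite-sites Jukes-Cantor evolution along one local genealogy over the
// half-open site interval [lo, hi).  The alignment matrix (tips x sites,
// base codes 0..3) must already hold the stationary root draw for every
// site; substitution events are a Poisson process at rate mu per site per
// generation on the branches, each replacing the current base with one of
// the three alternatives uniformly.  Uses R's RNG.
namespace jcmut {

struct Ev { int site; int branch; double t; };

inline void apply_site(const SegTree &T, const Ev *ev, int k,
                       Rcpp::RawMatrix &aln, int site) {
#ifdef DIVERGOME_DEBUG
  if (site < 0 || site >= aln.ncol())
    Rcpp::stop("apply_site: site %d out of range", site);
  if (T.root < 0 || T.root >= T.n_nodes())
    Rcpp::stop("apply_site: bad root %d", T.root);
#endif
  Rbyte rootbase = aln(0, site); // all rows identical before mutation
  std::vector<std::pair<int,Rbyte>> stack;
  stack.reserve(2 * T.n);
  stack.push_back({T.root, rootbase});
  std::vector<double> times;
#ifdef DIVERGOME_DEBUG
  int visited = 0;
#endif
  while (!stack.empty()) {
    int node = stack.back().first;
#ifdef DIVERGOME_DEBUG
    if (node < 0 || node >= T.n_nodes())
      Rcpp::stop("apply_site: bad node %d (root %d)", node, T.root);
    if (++visited > 4 * T.n_nodes())
      Rcpp::stop("apply_site: traversal cycle detected");
#endif
    Rbyte base = stack.back().second;
    stack.pop_back();
    // events on the branch above `node`, applied rootward-first
    times.clear();
    for (int e = 0; e < k; ++e) if (ev[e].branch == node) times.push_back(ev[e].t);
    if (!times.empty()) {
      std::sort(times.begin(), times.end(), std::greater<double>());
      for (size_t e = 0; e < times.size(); ++e) {
        base = (Rbyte)((base + 1 + (int)(R::unif_rand() * 3.0)) & 3);
      }
    }
    if (node < T.n) {
      aln(node, site) = base;
    } else {
      stack.push_back({T.c1[node], base});
      stack.push_back({T.c2[node], base});
    }
  }
}

inline int mutate_segment(const SegTree &T, double lo, double hi, double mu,
                          Rcpp::RawMatrix &aln) {
  double B = T.total_len();
  double len = hi - lo;
  if (len <= 0 || B <= 0 || mu <= 0) return 0;
  int nm = (int) R::rpois(mu * len * B);
  if (nm == 0) return 0;
  int M = T.n_nodes();
  std::vector<double> cum(M, 0.0);
  double acc = 0.0;
  for (int i = 0; i < M; ++i) {
    if (i != T.root) acc += T.branch_len(i);
    cum[i] = acc;
  }
  std::vector<Ev> evs; evs.reserve(nm);
  int ns = aln.ncol();
  for (int kk = 0; kk < nm; ++kk) {
    // breakpoints are continuous, so segments need not align with integer
    // sites; a site straddling a breakpoint receives its mutation mass
    // from both neighbouring segments in proportion to overlap
    int site = (int)(lo + R::unif_rand() * len);
    if (site >= ns) site = ns - 1;
    double u = R::unif_rand() * acc;
    int br = (int)(std::upper_bound(cum.begin(), cum.end(), u) - cum.begin());
    if (br >= M) br = M - 1;
    if (br == T.root) continue; // zero-length, unreachable in practice
    double tt = T.time[br] + R::unif_rand() * T.branch_len(br);
    evs.push_back({site, br, tt});
  }
  std::sort(evs.begin(), evs.end(),
            [](const Ev &a, const Ev &b){ return a.site < b.site; });
  size_t i = 0;
  while (i < evs.size()) {
    size_t j = i;
    int site = evs[i].site;
    while (j < evs.size() && evs[j].site == site) ++j;
    apply_site(T, &evs[i], (int)(j - i), aln, site);
    i = j;
  }
  return nm;
}

} // namespace jcmut

#endif
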