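#ifndef DIVERGOME_TREE_H
#define DIVERGOME_TREE_H

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <utility>

// A rooted binary genealogy over n sampled haplotypes with node times in
// generations (tips at time 0) and, for each non-root branch, a record of
// the deme occupied going rootward: deme0 at the child node, then a list of
// (time, new deme) switches.  Node ids 0..n-1 are tips; internal nodes are
// n..2n-2.  The same container is reused along the sequence by the SMC'
// updates, so ids are stable but times/topology mutate.
struct SegTree {
  int n = 0;                         // number of tips
  std::vector<int> parent, c1, c2;   // -1 where absent
  std::vector<double> time;          // node heights, generations
  std::vector<int> deme0;            // deme of branch just above node
  std::vector<std::vector<std::pair<double,int>>> migs; // per-branch switches
  int root = -1;

  int n_nodes() const { return 2 * n - 1; }

  void init(int n_) {
    n = n_;
    int m = 2 * n - 1;
    parent.assign(m, -1); c1.assign(m, -1); c2.assign(m, -1);
    time.assign(m, 0.0); deme0.assign(m, 0);
    migs.assign(m, {});
    root = -1;
  }

  double branch_len(int i) const {
    if (i == root) return 0.0;
    return time[parent[i]] - time[i];
  }

  double total_len() const {
    double s = 0.0;
    for (int i = 0; i < n_nodes(); ++i) if (i != root) s += branch_len(i);
    return s;
  }

  // deme of branch above node i at time t (time[i] <= t < time[parent[i]])
  int deme_at(int i, double t) const {
    int d = deme0[i];
    for (const auto &mv : migs[i]) {
      if (mv.first <= t) d = mv.second; else break;
    }
    return d;
  }

  // is branch i alive (present between its node and its parent) at time t?
  bool alive_at(int i, double t) const {
    if (i == root) return false;
    return time[i] <= t && t < time[parent[i]];
  }
};

#endif
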