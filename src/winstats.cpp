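// Per-window summaries of a two-population haplotype alignment: pooled
// polymorphic-site counts, Hudson F_ST components (within/between
// heterozygosity sums over polymorphic sites, "ratio of sums"), d_xy, and
// fixed-difference counts.  Base codes are 0..3; windows are 0-based
// half-open tiles of the sequence.

#include <Rcpp.h>
using namespace Rcpp;

// [[Rcpp::export]]
List window_stats_cpp(RawMatrix aln, IntegerVector pop, int window_bp) {
  int H = aln.nrow();
  int L = aln.ncol();
  if (pop.size() != H) stop("pop labels must match alignment rows");
  int n0 = 0, n1 = 0;
  for (int h = 0; h < H; ++h) {
    if (pop[h] == 0) ++n0; else if (pop[h] == 1) ++n1;
    else stop("pop labels must be 0 or 1");
  }
  if (n0 == 0 || n1 == 0) stop("both populations must be non-empty");
  int nwin = (L + window_bp - 1) / window_bp;

  IntegerVector w_start(nwin), w_end(nwin), w_poly(nwin), w_fixed(nwin);
  NumericVector w_hw(nwin), w_hb(nwin), w_dxy(nwin);

  for (int w = 0; w < nwin; ++w) {
    int lo = w * window_bp;
    int hi = std::min(L, lo + window_bp);
    int npoly = 0, nfixed = 0;
    double hw_sum = 0.0, hb_sum = 0.0, dxy_sum = 0.0;
    for (int s = lo; s < hi; ++s) {
      int c0[4] = {0, 0, 0, 0}, c1[4] = {0, 0, 0, 0};
      for (int h = 0; h < H; ++h) {
        int b = aln(h, s);
        if (b < 0 || b > 3) stop("invalid base code at row %d site %d", h + 1, s + 1);
        if (pop[h] == 0) ++c0[b]; else ++c1[b];
      }
      int nalleles = 0, b0 = -1, b1 = -1, m0 = 0, m1 = 0;
      for (int b = 0; b < 4; ++b) {
        if (c0[b] + c1[b] > 0) ++nalleles;
        if (c0[b] > 0) { ++m0; b0 = b; }
        if (c1[b] > 0) { ++m1; b1 = b; }
      }
      double cross = 0.0;
      for (int b = 0; b < 4; ++b) cross += (double)c0[b] * c1[b];
      double hb = 1.0 - cross / ((double)n0 * n1);
      dxy_sum += hb;
      if (nalleles >= 2) {
        ++npoly;
        double hw0 = 0.0, hw1 = 0.0;
        if (n0 >= 2) {
          double same = 0.0;
          for (int b = 0; b < 4; ++b) same += (double)c0[b] * (c0[b] - 1);
          hw0 = 1.0 - same / ((double)n0 * (n0 - 1));
        }
        if (n1 >= 2) {
          double same = 0.0;
          for (int b = 0; b < 4; ++b) same += (double)c1[b] * (c1[b] - 1);
          hw1 = 1.0 - same / ((double)n1 * (n1 - 1));
        }
        hw_sum += 0.5 * (hw0 + hw1);
        hb_sum += hb;
        if (m0 == 1 && m1 == 1 && b0 != b1) ++nfixed;
      }
    }
    w_start[w] = lo; w_end[w] = hi;
    w_poly[w] = npoly; w_fixed[w] = nfixed;
    w_hw[w] = hw_sum; w_hb[w] = hb_sum;
    w_dxy[w] = dxy_sum / (double)(hi - lo);
  }
  return List::create(
    _["start_bp"] = w_start, _["end_bp"] = w_end,
    _["n_poly"] = w_poly, _["n_fixed"] = w_fixed,
    _["hw_sum"] = w_hw, _["hb_sum"] = w_hb, _["dxy"] = w_dxy);
}
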