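// Monte Carlo simulator for labelled gene trees under the multi-species
// coalescent with piecewise-constant population sizes and no gene flow.
//
// The species tree arrives flattened: branches indexed 0..nbr-1 with parent
// pointers, plus a global time segmentation (all divergence times and epoch
// boundaries) and an (nbr x nseg) matrix of diploid sizes, -1 where a
// branch is inactive during a segment.  Within each segment, lineages
// grouped by their current branch coalesce with exponential waiting times
// at rate C(m,2)/(2*eta), truncated at the segment end; surviving lineages
// are handed to parent branches as segments pass divergence times.  The
// final segment (the root's unbounded epoch) runs to completion.
//
// Uses R's RNG (seed via set.seed() in the calling R code).

#include <Rcpp.h>
#include <vector>
#include <cstdint>
using namespace Rcpp;

// [[Rcpp::export]]
List sim_msc_cpp(IntegerVector lin_branch,   // 0-based home branch per lineage
                 IntegerVector br_parent,    // 0-based parent branch, -1 root
                 NumericVector seg_start,    // segment starts (last is root's)
                 NumericMatrix eta,          // nbr x nseg, -1 = inactive
                 int R) {
  const int n = lin_branch.size();
  const int nbr = br_parent.size();
  const int nseg = seg_start.size();
  const int nnode = 2 * n - 1;
  const int npair = n * (n - 1) / 2;

  IntegerMatrix parent(R, nnode);
  NumericMatrix times(R, nnode);
  NumericMatrix pair_t(R, npair);

  // pair index lookup (i < j, 0-based), matching R's combn(n, 2) order
  std::vector<int> poff(n);
  {
    int k = 0;
    for (int i = 0; i < n; ++i) { poff[i] = k - i - 1; k += n - i - 1; }
  }

  std::vector<int> cl_branch(n), cl_node(n);
  std::vector<uint64_t> cl_mask(n);
  std::vector<int> grp;     // cluster indices in the current branch
  grp.reserve(n);

  for (int rep = 0; rep < R; ++rep) {
    int ncl = n;
    int next_node = n;
    for (int i = 0; i < n; ++i) {
      cl_branch[i] = lin_branch[i];
      cl_node[i] = i;
      cl_mask[i] = (uint64_t)1 << i;
      parent(rep, i) = -1;
      times(rep, i) = 0.0;
    }
    for (int v = n; v < nnode; ++v) { parent(rep, v) = -1; times(rep, v) = 0.0; }

    for (int seg = 0; seg < nseg && ncl > 1; ++seg) {
      const double t0 = seg_start[seg];
      const double t1 = (seg + 1 < nseg) ? seg_start[seg + 1] : R_PosInf;
      // promote clusters whose branch is inactive here to an active ancestor
      for (int c = 0; c < ncl; ++c) {
        int b = cl_branch[c];
        while (eta(b, seg) < 0.0 && br_parent[b] >= 0) b = br_parent[b];
        cl_branch[c] = b;
      }
      // coalesce within each branch hosting >= 2 clusters
      for (int b = 0; b < nbr && ncl > 1; ++b) {
        const double e = eta(b, seg);
        if (e < 0.0) continue;
        grp.clear();
        for (int c = 0; c < ncl; ++c) if (cl_branch[c] == b) grp.push_back(c);
        int m = (int)grp.size();
        if (m < 2) continue;
        double t = t0;
        while (m >= 2) {
          const double rate = m * (m - 1) / 2.0 / (2.0 * e);
          t += exp_rand() / rate;
          if (t >= t1) break;
          // uniform random pair among the m clusters in this branch
          int a = (int)(unif_rand() * m); if (a == m) a = m - 1;
          int bsel = (int)(unif_rand() * (m - 1)); if (bsel == m - 1) bsel = m - 2;
          if (bsel >= a) ++bsel;
          int ca = grp[a], cb = grp[bsel];
          // record pairwise MRCA times between the two tip sets
          for (int i = 0; i < n; ++i) {
            if (!(cl_mask[ca] >> i & 1)) continue;
            for (int j = 0; j < n; ++j) {
              if (!(cl_mask[cb] >> j & 1)) continue;
              int lo = i < j ? i : j, hi = i < j ? j : i;
              pair_t(rep, poff[lo] + hi) = t;
            }
          }
          // merge cb into ca, new gene-tree node
          times(rep, next_node) = t;
          parent(rep, cl_node[ca]) = next_node;
          parent(rep, cl_node[cb]) = next_node;
          cl_node[ca] = next_node;
          cl_mask[ca] |= cl_mask[cb];
          ++next_node;
          // drop cluster cb: move the last cluster into its slot
          int last = ncl - 1;
          if (cb != last) {
            cl_branch[cb] = cl_branch[last];
            cl_node[cb] = cl_node[last];
            cl_mask[cb] = cl_mask[last];
          }
          --ncl;
          // rebuild the branch group
          grp.clear();
          for (int c = 0; c < ncl; ++c) if (cl_branch[c] == b) grp.push_back(c);
          m = (int)grp.size();
        }
      }
    }
  }
  return List::create(_["parent"] = parent, _["times"] = times,
                      _["pair_times"] = pair_t);
}
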