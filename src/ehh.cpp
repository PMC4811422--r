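#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Haplotype-group bookkeeping for the outward EHHS walk.
//
// Haplotypes identical over the current span share a group id in g
// (dense ids in [0, n_groups)).  Extending the span by one SNP splits
// each group by the allele carried there; homozygosity is the unbiased
// pairwise identity probability sum n_k (n_k - 1) / (n (n - 1)).

static double group_homozygosity(const std::vector<int> &g, int n_groups) {
  std::vector<int> cnt(n_groups, 0);
  for (size_t i = 0; i < g.size(); ++i) cnt[g[i]]++;
  double n = (double)g.size();
  double s = 0.0;
  for (int k = 0; k < n_groups; ++k) s += (double)cnt[k] * (cnt[k] - 1.0);
  return s / (n * (n - 1.0));
}

// split groups by the allele column j; returns new group count
static int split_groups(std::vector<int> &g, const IntegerMatrix &hap, int j) {
  int n = g.size();
  int old_groups = 0;
  for (int i = 0; i < n; ++i) if (g[i] >= old_groups) old_groups = g[i] + 1;
  std::vector<int> remap(2 * old_groups, -1);
  int next_id = 0;
  for (int i = 0; i < n; ++i) {
    int key = 2 * g[i] + hap(i, j);
    if (remap[key] < 0) remap[key] = next_id++;
    g[i] = remap[key];
  }
  return next_id;
}

static int init_groups(std::vector<int> &g, const IntegerMatrix &hap, int focal) {
  int n = hap.nrow();
  g.assign(n, 0);
  int id0 = -1, id1 = -1, next_id = 0;
  for (int i = 0; i < n; ++i) {
    if (hap(i, focal) == 0) {
      if (id0 < 0) id0 = next_id++;
      g[i] = id0;
    } else {
      if (id1 < 0) id1 = next_id++;
      g[i] = id1;
    }
  }
  return next_id;
}

// One flank of the EHHS profile: evaluate at successive SNPs outward from
// `focal` in direction `dir` (+1 right, -1 left), stopping after the first
// value strictly below `cutoff` or at the chromosome end (truncation).
// Returns evaluated indices (0-based), EHHS values, truncation flag.
static void walk_flank(const IntegerMatrix &hap, int focal, int dir,
                       double cutoff, double h0,
                       std::vector<int> &idx_out, std::vector<double> &ehhs_out,
                       bool &truncated) {
  int S = hap.ncol();
  std::vector<int> g;
  int ng = init_groups(g, hap, focal);
  truncated = true;  // stays true if we never drop below cutoff
  for (int j = focal + dir; j >= 0 && j < S; j += dir) {
    ng = split_groups(g, hap, j);
    double e = (h0 > 0.0) ? group_homozygosity(g, ng) / h0 : 0.0;
    idx_out.push_back(j);
    ehhs_out.push_back(e);
    if (e < cutoff) { truncated = false; break; }
  }
  // zero-length flank (focal at chromosome end): truncated by definition
}

// [[Rcpp::export(name = ".ehhs_walk_cpp")]]
List ehhs_walk_cpp(IntegerMatrix hap, int focal0, double cutoff) {
  int n = hap.nrow();
  if (n < 2) stop("need at least 2 haplotypes");
  std::vector<int> g;
  int ng = init_groups(g, hap, focal0);
  double h0 = group_homozygosity(g, ng);

  std::vector<int> li, ri;
  std::vector<double> le, re;
  bool tl, tr;
  walk_flank(hap, focal0, -1, cutoff, h0, li, le, tl);
  walk_flank(hap, focal0, +1, cutoff, h0, ri, re, tr);

  return List::create(
    _["h0"] = h0,
    _["left_idx"] = wrap(li), _["left_ehhs"] = wrap(le),
    _["right_idx"] = wrap(ri), _["right_ehhs"] = wrap(re),
    _["truncated_left"] = tl, _["truncated_right"] = tr);
}

// Per-SNP iES for one chromosome: trapezoid integral of EHHS over bp on
// each flank, out to (and including) the first SNP below cutoff.  SNPs
// failing the MAF floor get NA; truncated profiles get NA when
// discard_at_border is set.
// [[Rcpp::export(name = ".ies_scan_cpp")]]
NumericVector ies_scan_cpp(IntegerMatrix hap, NumericVector pos,
                           double cutoff, double maf_floor,
                           bool discard_at_border) {
  int n = hap.nrow(), S = hap.ncol();
  if (n < 2) stop("need at least 2 haplotypes");
  NumericVector ies(S, NA_REAL);
  for (int focal = 0; focal < S; ++focal) {
    double f = 0.0;
    for (int i = 0; i < n; ++i) f += hap(i, focal);
    f /= n;
    double maf = f < 0.5 ? f : 1.0 - f;
    if (maf < maf_floor) continue;

    std::vector<int> g;
    int ng = init_groups(g, hap, focal);
    double h0 = group_homozygosity(g, ng);
    if (h0 <= 0.0) continue;

    double area = 0.0;
    bool truncated_any = false;
    for (int dir = -1; dir <= 1; dir += 2) {
      ng = init_groups(g, hap, focal);
      double prev_e = 1.0, prev_p = pos[focal];
      bool below = false;
      int j;
      for (j = focal + dir; j >= 0 && j < S; j += dir) {
        ng = split_groups(g, hap, j);
        double e = group_homozygosity(g, ng) / h0;
        area += 0.5 * (prev_e + e) * std::abs(pos[j] - prev_p);
        prev_e = e; prev_p = pos[j];
        if (e < cutoff) { below = true; break; }
      }
      if (!below) truncated_any = true;  // hit chromosome end above cutoff
    }
    if (truncated_any && discard_at_border) continue;
    ies[focal] = area;
  }
  return ies;
}
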