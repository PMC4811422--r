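#include <Rcpp.h>
#include <vector>
#include <set>
#include <algorithm>
#include <cstring>
using namespace Rcpp;

// Forward Wright-Fisher simulator for two-population sweep panels.
//
// Discrete generations, N diploids per population (2N haplotypes),
// infinite-sites mutation onto integer bp positions with collision
// re-draw, Poisson crossovers, genic selection (fitness 1, 1+s, 1+2s)
// at a single site in population 1 after the split.  Haplotypes live
// in flat row-major buffers (one byte per site, columns in
// mutation-arrival order); recombination only needs each site's bp
// position, so position-sorting happens once at sampling time.
//
// All randomness flows through R's RNG (unif_rand / R::rpois), so a
// set.seed() on the R side makes runs bit-reproducible.

struct FlatPop {
  int n2;            // haplotype rows
  size_t cap;        // column capacity (row stride)
  std::vector<unsigned char> buf;
  explicit FlatPop(int n2_) : n2(n2_), cap(64), buf((size_t)n2_ * 64, 0) {}
  unsigned char *row(int i) { return &buf[(size_t)i * cap]; }
  const unsigned char *row(int i) const { return &buf[(size_t)i * cap]; }
  void ensure_cap(size_t S_needed) {
    if (S_needed <= cap) return;
    size_t nc = cap;
    while (nc < S_needed) nc *= 2;
    std::vector<unsigned char> nb((size_t)n2 * nc, 0);
    for (int i = 0; i < n2; ++i)
      std::memcpy(&nb[(size_t)i * nc], row(i), cap);
    buf.swap(nb);
    cap = nc;
  }
};

static int weighted_pick(const std::vector<double> &cumw) {
  double u = unif_rand() * cumw.back();
  return std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin();
}

// gamete from one diploid parent (rows 2p, 2p+1) into `child`
static void make_gamete(const FlatPop &pop, int parent,
                        const std::vector<double> &pos, double L,
                        double rec_total, unsigned char *child, size_t S) {
  const unsigned char *h0 = pop.row(2 * parent);
  const unsigned char *h1 = pop.row(2 * parent + 1);
  int start = unif_rand() < 0.5 ? 0 : 1;
  int k = (int)R::rpois(rec_total);
  if (k == 0) {
    std::memcpy(child, start ? h1 : h0, S);
    return;
  }
  if (k == 1) {
    double bp = unif_rand() * L;
    const unsigned char *a = start ? h1 : h0;
    const unsigned char *b = start ? h0 : h1;
    for (size_t j = 0; j < S; ++j) child[j] = pos[j] < bp ? a[j] : b[j];
    return;
  }
  std::vector<double> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = unif_rand() * L;
  std::sort(bp.begin(), bp.end());
  for (size_t j = 0; j < S; ++j) {
    int nx = std::upper_bound(bp.begin(), bp.end(), pos[j]) - bp.begin();
    child[j] = ((start + nx) & 1) ? h1[j] : h0[j];
  }
}

// one WF generation; sel_col < 0 means neutral
static void generation(FlatPop &pop, FlatPop &next,
                       const std::vector<double> &pos, size_t S,
                       double L, double rec_total, int sel_col, double s) {
  int N = pop.n2 / 2;
  next.ensure_cap(S);
  std::vector<double> cumw(N);
  double acc = 0.0;
  for (int i = 0; i < N; ++i) {
    double w = 1.0;
    if (sel_col >= 0) {
      int g = pop.row(2 * i)[sel_col] + pop.row(2 * i + 1)[sel_col];
      w = 1.0 + s * g;
    }
    acc += w;
    cumw[i] = acc;
  }
  for (int i = 0; i < N; ++i) {
    int pa = weighted_pick(cumw);
    int pb = weighted_pick(cumw);
    make_gamete(pop, pa, pos, L, rec_total, next.row(2 * i), S);
    make_gamete(pop, pb, pos, L, rec_total, next.row(2 * i + 1), S);
  }
  std::swap(pop.buf, next.buf);
  std::swap(pop.cap, next.cap);
}

// add this generation's new mutations (batched column appends; absent
// columns are zero in every population sharing the column space)
static void mutate_all(std::vector<FlatPop *> &pops,
                       std::vector<double> &pos, std::set<long> &used,
                       double L, double mu, size_t &S) {
  size_t n_pops = pops.size();
  std::vector<int> nmut(n_pops);
  int total = 0;
  for (size_t q = 0; q < n_pops; ++q) {
    nmut[q] = (int)R::rpois(mu * L * pops[q]->n2);
    total += nmut[q];
  }
  if (total == 0) return;
  for (size_t q = 0; q < n_pops; ++q) {
    pops[q]->ensure_cap(S + total);
    for (int i = 0; i < pops[q]->n2; ++i)
      std::memset(pops[q]->row(i) + S, 0, total);
  }
  int col = S;
  for (size_t q = 0; q < n_pops; ++q)
    for (int m = 0; m < nmut[q]; ++m, ++col) {
      long p;
      do { p = (long)(unif_rand() * L) + 1; } while (used.count(p));
      used.insert(p);
      pos.push_back((double)p);
      int carrier = (int)(unif_rand() * pops[q]->n2);
      if (carrier >= pops[q]->n2) carrier = pops[q]->n2 - 1;
      pops[q]->row(carrier)[col] = 1;
    }
  S += total;
}

static void col_counts(const FlatPop &pop, size_t S, std::vector<int> &cnt) {
  cnt.assign(S, 0);
  for (int i = 0; i < pop.n2; ++i) {
    const unsigned char *r = pop.row(i);
    for (size_t j = 0; j < S; ++j) cnt[j] += r[j];
  }
}

// drop columns lost everywhere or fixed everywhere; remap sel_col
static void purge(std::vector<FlatPop *> &pops, std::vector<double> &pos,
                  size_t &S, int &sel_col) {
  std::vector<int> total(S, 0);
  int cap_n = 0;
  for (size_t q = 0; q < pops.size(); ++q) {
    std::vector<int> cnt;
    col_counts(*pops[q], S, cnt);
    for (size_t j = 0; j < S; ++j) total[j] += cnt[j];
    cap_n += pops[q]->n2;
  }
  std::vector<int> keep;
  keep.reserve(S);
  int new_sel = -1;
  for (size_t j = 0; j < S; ++j) {
    bool lost = total[j] == 0, fixed = total[j] == cap_n;
    // a column fixed in one population but not the other stays (it is
    // a between-population difference); only globally lost/fixed go
    if (!(lost || fixed) || (int)j == sel_col) {
      if ((int)j == sel_col) new_sel = keep.size();
      keep.push_back(j);
    }
  }
  std::vector<double> np(keep.size());
  for (size_t k = 0; k < keep.size(); ++k) np[k] = pos[keep[k]];
  pos.swap(np);
  for (size_t q = 0; q < pops.size(); ++q)
    for (int i = 0; i < pops[q]->n2; ++i) {
      unsigned char *r = pops[q]->row(i);
      for (size_t k = 0; k < keep.size(); ++k) r[k] = r[keep[k]];
    }
  S = keep.size();
  sel_col = new_sel;
}

static double col_freq(const FlatPop &pop, int j) {
  if (j < 0) return NA_REAL;
  int c = 0;
  for (int i = 0; i < pop.n2; ++i) c += pop.row(i)[j];
  return (double)c / pop.n2;
}

// sample n_ind diploids (2*n_ind haplotype rows) without replacement
static std::vector<int> sample_rows(int N, int n_ind) {
  std::vector<int> idx(N);
  for (int i = 0; i < N; ++i) idx[i] = i;
  for (int i = 0; i < n_ind; ++i) {
    int j = i + (int)(unif_rand() * (N - i));
    if (j >= N) j = N - 1;
    std::swap(idx[i], idx[j]);
  }
  std::vector<int> rows;
  for (int i = 0; i < n_ind; ++i) {
    rows.push_back(2 * idx[i]);
    rows.push_back(2 * idx[i] + 1);
  }
  return rows;
}

// [[Rcpp::export(name = ".wf_sim_cpp")]]
List wf_sim_cpp(int N, double L, double mu, double rec,
                int burnin, int split_gens, double s, double sel_pos,
                double standing_freq_min, double standing_freq_max,
                int n_sample, int max_retries, int purge_every) {
  int n2 = 2 * N;
  if (n_sample % 2 != 0 || n_sample > n2)
    stop("n_sample must be even and at most 2N");
  double rec_total = rec * L;

  FlatPop pop1(n2), scratch(n2);
  std::vector<double> pos;
  std::set<long> used;
  size_t S = 0;
  int sel_col = -1;

  std::vector<FlatPop *> one;
  one.push_back(&pop1);

  // burn-in: neutral standing variation in the ancestral population
  for (int g = 0; g < burnin; ++g) {
    generation(pop1, scratch, pos, S, L, rec_total, -1, 0.0);
    mutate_all(one, pos, used, L, mu, S);
    if ((g + 1) % purge_every == 0) purge(one, pos, S, sel_col);
  }
  purge(one, pos, S, sel_col);

  // pick the selected site: segregating column nearest sel_pos with
  // standing derived-allele frequency in
  // [standing_freq_min, standing_freq_max] (young rare standing
  // variant -> hard-sweep regime)
  {
    std::vector<int> cnt;
    col_counts(pop1, S, cnt);
    double best = -1.0;
    int lo = (int)std::max(1.0, standing_freq_min * n2);
    int hi = (int)std::max(1.0, standing_freq_max * n2);
    for (size_t j = 0; j < S; ++j) {
      if (cnt[j] < lo || cnt[j] > hi) continue;
      if (best < 0 || std::abs(pos[j] - sel_pos) < best) {
        best = std::abs(pos[j] - sel_pos);
        sel_col = j;
      }
    }
    if (sel_col < 0) stop("no segregating site available to select on");
  }

  // split: population 2 is a copy of population 1 at the split
  FlatPop pop1_save = pop1;
  std::vector<double> pos_save = pos;
  size_t S_save = S;
  int sel_save = sel_col;
  double split_freq = col_freq(pop1, sel_col);

  FlatPop pop2(n2), scratch2(n2);
  std::vector<FlatPop *> both;
  int retries = 0;
  bool ok = false;
  while (!ok && retries <= max_retries) {
    pop1 = pop1_save;
    pop2 = pop1_save;
    pos = pos_save;
    S = S_save;
    sel_col = sel_save;
    both.clear();
    both.push_back(&pop1);
    both.push_back(&pop2);
    ok = true;
    for (int g = 0; g < split_gens; ++g) {
      generation(pop1, scratch, pos, S, L, rec_total,
                 s > 0 ? sel_col : -1, s);
      generation(pop2, scratch2, pos, S, L, rec_total, -1, 0.0);
      mutate_all(both, pos, used, L, mu, S);
      if (s > 0 && col_freq(pop1, sel_col) == 0.0) { ok = false; break; }
      if ((g + 1) % purge_every == 0) purge(both, pos, S, sel_col);
    }
    if (!ok) retries++;
  }
  if (!ok) stop("selected allele lost in every attempt (%d retries)", retries);
  purge(both, pos, S, sel_col);

  double f1 = col_freq(pop1, sel_col), f2 = col_freq(pop2, sel_col);

  // sample diploids from each population
  std::vector<int> rows1 = sample_rows(N, n_sample / 2);
  std::vector<int> rows2 = sample_rows(N, n_sample / 2);

  // retain columns segregating in the pooled sample, in position order
  std::vector<int> cnt(S, 0);
  for (size_t r = 0; r < rows1.size(); ++r) {
    const unsigned char *h = pop1.row(rows1[r]);
    for (size_t j = 0; j < S; ++j) cnt[j] += h[j];
  }
  for (size_t r = 0; r < rows2.size(); ++r) {
    const unsigned char *h = pop2.row(rows2[r]);
    for (size_t j = 0; j < S; ++j) cnt[j] += h[j];
  }
  int cap = rows1.size() + rows2.size();
  std::vector<int> keep;
  for (size_t j = 0; j < S; ++j)
    if (cnt[j] > 0 && cnt[j] < cap) keep.push_back(j);
  std::sort(keep.begin(), keep.end(),
            [&pos](int a, int b) { return pos[a] < pos[b]; });

  int Sk = keep.size();
  IntegerMatrix m1(rows1.size(), Sk), m2(rows2.size(), Sk);
  NumericVector out_pos(Sk);
  for (int k = 0; k < Sk; ++k) out_pos[k] = pos[keep[k]];
  for (size_t r = 0; r < rows1.size(); ++r)
    for (int k = 0; k < Sk; ++k) m1(r, k) = pop1.row(rows1[r])[keep[k]];
  for (size_t r = 0; r < rows2.size(); ++r)
    for (int k = 0; k < Sk; ++k) m2(r, k) = pop2.row(rows2[r])[keep[k]];

  return List::create(
    _["hap1"] = m1, _["hap2"] = m2, _["positions"] = out_pos,
    _["selected_pos"] = pos[sel_col < 0 ? 0 : sel_col],
    _["selected_freq_split"] = split_freq,
    _["selected_freq_pop1"] = f1, _["selected_freq_pop2"] = f2,
    _["retries"] = retries);
}
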