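#include <Rcpp.h>
#include <vector>
#include <cstring>
#include <algorithm>
using namespace Rcpp;

// Discrete-generation diploid Wright-Fisher forward simulator with a
// sparse segregating-site representation: only currently polymorphic
// columns are stored, in two flat row-major buffers that are reused
// across generations. Genotype fitnesses at the selected site are
// 1, 1+hs, 1+s. Crossovers fall between adjacent base pairs at rate
// `rec` per pair per gamete; mutations arise at rate `mu` per site per
// generation, at most one retained per site (infinite-sites
// approximation). Uses R's RNG so set.seed() governs reproducibility.

struct Pop {
  int n2;                       // chromosomes (2N)
  int S;                        // current segregating columns
  int cap;                      // column capacity of the buffers
  std::vector<unsigned char> cur, nxt;
  std::vector<int> pos;         // 1-based positions of the columns
  int sel;                      // selected column index, -1 if none

  void init(int n2_, int cap_) {
    n2 = n2_;
    S = 0;
    cap = cap_;
    cur.assign((size_t)n2 * cap, 0);
    nxt.assign((size_t)n2 * cap, 0);
    pos.clear();
    sel = -1;
  }
  void grow(int need) {
    if (need <= cap) return;
    int newcap = std::max(need, cap * 2);
    std::vector<unsigned char> a((size_t)n2 * newcap, 0);
    for (int g = 0; g < n2; ++g)
      std::memcpy(&a[(size_t)g * newcap], &cur[(size_t)g * cap], S);
    cur.swap(a);
    nxt.assign((size_t)n2 * newcap, 0);
    cap = newcap;
  }
  unsigned char* row(int g) { return &cur[(size_t)g * cap]; }
};

static void next_generation(Pop& pop, int N, int L, double mu, double rec,
                            double s, double h) {
  const int n2 = pop.n2;
  const int S = pop.S;
  const bool selection = pop.sel >= 0 && s > 0;
  static std::vector<double> cumw;
  if (selection) {
    cumw.resize(N);
    double acc = 0.0;
    for (int i = 0; i < N; ++i) {
      int g = pop.row(2 * i)[pop.sel] + pop.row(2 * i + 1)[pop.sel];
      acc += (g == 1) ? 1.0 + h * s : (g == 2 ? 1.0 + s : 1.0);
      cumw[i] = acc;
    }
  }
  int br[64];
  for (int g = 0; g < n2; ++g) {
    int p;
    if (selection) {
      double u = unif_rand() * cumw[N - 1];
      p = std::lower_bound(cumw.begin(), cumw.end(), u) - cumw.begin();
    } else {
      p = (int)(unif_rand() * N);
    }
    const unsigned char* hA = pop.row(2 * p);
    const unsigned char* hB = pop.row(2 * p + 1);
    unsigned char* child = &pop.nxt[(size_t)g * pop.cap];
    int start = (unif_rand() < 0.5) ? 0 : 1;
    int ncx = (int)R::rpois(rec * (L - 1));
    if (ncx == 0) {
      std::memcpy(child, start == 0 ? hA : hB, S);
    } else {
      if (ncx > 64) ncx = 64;   // vanishingly unlikely at realistic rates
      for (int b = 0; b < ncx; ++b) br[b] = 1 + (int)(unif_rand() * (L - 1));
      for (int j = 0; j < S; ++j) {
        int cnt = 0;
        for (int b = 0; b < ncx; ++b) if (br[b] < pop.pos[j]) ++cnt;
        child[j] = ((start + cnt) & 1) == 0 ? hA[j] : hB[j];
      }
    }
  }
  pop.cur.swap(pop.nxt);
  // new mutations (one per distinct site)
  int nmut = (int)R::rpois(2.0 * N * (double)L * mu);
  if (nmut > 0) {
    pop.grow(pop.S + nmut);
    for (int m = 0; m < nmut; ++m) {
      int p = 1 + (int)(unif_rand() * L);
      if (std::find(pop.pos.begin(), pop.pos.end(), p) != pop.pos.end())
        continue;
      int c = (int)(unif_rand() * n2);
      int j = pop.S;
      for (int g = 0; g < n2; ++g) pop.row(g)[j] = 0;
      pop.row(c)[j] = 1;
      pop.pos.push_back(p);
      ++pop.S;
    }
  }
  // prune lost and fixed columns (always keep the selected column)
  const int Snow = pop.S;
  static std::vector<int> counts;
  counts.assign(Snow, 0);
  for (int g = 0; g < n2; ++g) {
    const unsigned char* r = pop.row(g);
    for (int j = 0; j < Snow; ++j) counts[j] += r[j];
  }
  static std::vector<int> keep;
  keep.clear();
  int new_sel = -1;
  for (int j = 0; j < Snow; ++j) {
    bool is_sel = (j == pop.sel);
    if (is_sel || (counts[j] > 0 && counts[j] < n2)) {
      if (is_sel) new_sel = (int)keep.size();
      keep.push_back(j);
    }
  }
  if ((int)keep.size() < Snow) {
    for (int g = 0; g < n2; ++g) {
      unsigned char* r = pop.row(g);
      for (size_t t = 0; t < keep.size(); ++t) r[t] = r[keep[t]];
    }
    for (size_t t = 0; t < keep.size(); ++t) pop.pos[t] = pop.pos[keep[t]];
    pop.pos.resize(keep.size());
    pop.S = (int)keep.size();
  }
  pop.sel = new_sel;
}

static int sel_count(Pop& pop) {
  if (pop.sel < 0) return 0;
  int c = 0;
  for (int g = 0; g < pop.n2; ++g) c += pop.row(g)[pop.sel];
  return c;
}

// [[Rcpp::export]]
List wf_simulate_cpp(int N, int L, double mu, double rec, double s, double h,
                     int sweep_site, int sample_n, double sampling_freq,
                     int burn_in, int max_restarts, int max_gen_per_attempt) {
  const int n2 = 2 * N;
  Pop pop;
  pop.init(n2, 256);
  for (int g = 0; g < burn_in; ++g) next_generation(pop, N, L, mu, rec, 0.0, h);

  std::vector<double> traj;
  int restarts = 0;
  if (s > 0) {
    int target = (int)std::ceil(sampling_freq * n2);
    // snapshot of the burned-in population for restarts
    std::vector<unsigned char> saved_buf = pop.cur;
    std::vector<int> saved_pos = pop.pos;
    int saved_S = pop.S, saved_cap = pop.cap;
    bool done = false;
    while (!done) {
      if (restarts > max_restarts)
        stop("selected allele lost in all %d restart attempts", max_restarts);
      pop.cur = saved_buf;
      pop.nxt.assign(saved_buf.size(), 0);
      pop.pos = saved_pos;
      pop.S = saved_S;
      pop.cap = saved_cap;
      // introduce a single selected copy at the sweep site
      int existing = -1;
      for (int j = 0; j < pop.S; ++j)
        if (pop.pos[j] == sweep_site) { existing = j; break; }
      if (existing >= 0) {
        // site occupied by a standing variant: clear it and reuse the column
        for (int g = 0; g < n2; ++g) pop.row(g)[existing] = 0;
        pop.sel = existing;
      } else {
        pop.grow(pop.S + 1);
        for (int g = 0; g < n2; ++g) pop.row(g)[pop.S] = 0;
        pop.pos.push_back(sweep_site);
        pop.sel = pop.S;
        ++pop.S;
      }
      int c0 = (int)(unif_rand() * n2);
      pop.row(c0)[pop.sel] = 1;
      traj.clear();
      traj.push_back(1.0 / n2);
      int gen = 0;
      while (true) {
        if (++gen > max_gen_per_attempt)
          stop("sweep did not resolve within %d generations", max_gen_per_attempt);
        next_generation(pop, N, L, mu, rec, s, h);
        int c = sel_count(pop);
        traj.push_back((double)c / n2);
        if (c == 0) { ++restarts; break; }
        if (c >= target) { done = true; break; }
      }
    }
  }

  // sample chromosomes without replacement
  std::vector<int> idx(n2);
  for (int i = 0; i < n2; ++i) idx[i] = i;
  for (int i = 0; i < sample_n; ++i) {
    int j = i + (int)(unif_rand() * (n2 - i));
    std::swap(idx[i], idx[j]);
  }
  IntegerMatrix sample(sample_n, pop.S);
  for (int i = 0; i < sample_n; ++i)
    for (int j = 0; j < pop.S; ++j)
      sample(i, j) = pop.row(idx[i])[j];

  return List::create(
    _["sample"] = sample,
    _["positions"] = IntegerVector(pop.pos.begin(), pop.pos.end()),
    _["sel_index"] = pop.sel + 1,
    _["final_freq"] = (s > 0 && pop.sel >= 0) ? (double)sel_count(pop) / n2 : NA_REAL,
    _["trajectory"] = NumericVector(traj.begin(), traj.end()),
    _["restarts"] = restarts);
}
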