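// Forward-in-time diploid Wright-Fisher simulator for one contig.
// Two-population split with optional founder bottleneck in the highland
// population and an optional hard sweep private to one population.
// Uses R's RNG throughout so set.seed() in R gives byte-identical replays.

#include <Rcpp.h>
#include <unordered_set>
#include <algorithm>
#include <numeric>
using namespace Rcpp;

typedef std::vector<uint8_t> Hap;
typedef std::vector<Hap> HapPool;   // 2N rows, one per haplotype

namespace {

int runif_int(int n) {
  // uniform integer in [0, n)
  int k = (int)(unif_rand() * n);
  if (k >= n) k = n - 1;
  return k;
}

// Build one gamete from parent haplotypes a and b.
// Crossover count ~ Poisson(rho * L), uniform breakpoints, no interference.
Hap make_gamete(const Hap& a, const Hap& b, const std::vector<int>& pos,
                double rho, int L) {
  int k = (int)R::rpois(rho * (double)L);
  bool start_b = unif_rand() < 0.5;
  if (k == 0) return start_b ? b : a;
  std::vector<double> bp(k);
  for (int i = 0; i < k; ++i) bp[i] = unif_rand() * L;
  size_t S = pos.size();
  Hap g(S);
  for (size_t j = 0; j < S; ++j) {
    int c = 0;
    for (int i = 0; i < k; ++i) if (bp[i] < pos[j]) ++c;
    bool use_b = start_b ^ (c & 1);
    g[j] = use_b ? b[j] : a[j];
  }
  return g;
}

// One generation of reproduction: Noff diploid offspring from pool `par`
// (Npar individuals). If sweep_idx >= 0 and s > 0, parents are sampled
// proportional to viability 1, 1+hs, 1+s by genotype at sweep_idx.
void reproduce(const HapPool& par, int Npar, int Noff, HapPool& off,
               const std::vector<int>& pos, double rho, int L,
               int sweep_idx, double s, double h) {
  off.clear();
  off.reserve(2 * (size_t)Noff);
  std::vector<double> cw;
  bool selected = sweep_idx >= 0 && s > 0;
  if (selected) {
    cw.resize(Npar);
    double acc = 0.0;
    for (int i = 0; i < Npar; ++i) {
      int gt = par[2 * i][sweep_idx] + par[2 * i + 1][sweep_idx];
      double w = gt == 0 ? 1.0 : (gt == 1 ? 1.0 + h * s : 1.0 + s);
      acc += w;
      cw[i] = acc;
    }
  }
  for (int i = 0; i < Noff; ++i) {
    for (int m = 0; m < 2; ++m) {
      int p;
      if (selected) {
        double u = unif_rand() * cw[Npar - 1];
        p = (int)(std::lower_bound(cw.begin(), cw.end(), u) - cw.begin());
        if (p >= Npar) p = Npar - 1;
      } else {
        p = runif_int(Npar);
      }
      off.push_back(make_gamete(par[2 * p], par[2 * p + 1], pos, rho, L));
    }
  }
}

// Add new mutations to a pool; at most one mutation ever retained per site
// (collisions with any position ever used are dropped and counted).
void mutate(HapPool& pool, HapPool& other, std::vector<int>& pos,
            std::unordered_set<int>& used, double mu, int L, long& collisions) {
  int nh = (int)pool.size();
  int M = (int)R::rpois((double)nh * mu * (double)L);
  for (int m = 0; m < M; ++m) {
    int r = runif_int(nh);
    int p = 1 + runif_int(L);
    if (used.count(p)) { ++collisions; continue; }
    used.insert(p);
    pos.push_back(p);
    for (auto& hp : pool) hp.push_back(0);
    for (auto& hp : other) hp.push_back(0);
    pool[r].back() = 1;
  }
}

// Drop columns lost or fixed across all current haplotypes (never the
// sweep column). Returns the new index of the sweep column.
int compact(std::vector<HapPool*> pools, std::vector<int>& pos, int sweep_idx) {
  size_t S = pos.size();
  if (S == 0) return sweep_idx;
  size_t total = 0;
  for (auto* pl : pools) total += pl->size();
  std::vector<size_t> cnt(S, 0);
  for (auto* pl : pools)
    for (auto& hp : *pl)
      for (size_t j = 0; j < S; ++j) cnt[j] += hp[j];
  std::vector<size_t> keep;
  keep.reserve(S);
  int new_sweep = -1;
  for (size_t j = 0; j < S; ++j) {
    bool k = (cnt[j] > 0 && cnt[j] < total) || (int)j == sweep_idx;
    if (k) {
      if ((int)j == sweep_idx) new_sweep = (int)keep.size();
      keep.push_back(j);
    }
  }
  if (keep.size() == S) return sweep_idx;
  std::vector<int> np(keep.size());
  for (size_t j = 0; j < keep.size(); ++j) np[j] = pos[keep[j]];
  pos.swap(np);
  for (auto* pl : pools)
    for (auto& hp : *pl) {
      Hap nh(keep.size());
      for (size_t j = 0; j < keep.size(); ++j) nh[j] = hp[keep[j]];
      hp.swap(nh);
    }
  return new_sweep;
}

int count_allele(const HapPool& pool, int idx) {
  int c = 0;
  for (auto& hp : pool) c += hp[idx];
  return c;
}

} // namespace

// [[Rcpp::export]]
List wf_sim_contig(int L, int n_anc, int n_low, int n_high,
                   double bottleneck_frac, int bottleneck_gens,
                   int t_split, int t_total, double mu, double rho,
                   int sweep_pos, double sweep_s, double sweep_h, int t_onset,
                   int sweep_target_high, int sample_low, int sample_high,
                   int max_reseed) {
  if (t_split > t_total) stop("t_split must be <= t_total");
  std::vector<int> pos;
  std::unordered_set<int> used;
  long collisions = 0;
  int reseeds = 0;
  int sweep_idx = -1;
  HapPool anc(2 * (size_t)n_anc), low, high, tmp;
  HapPool empty_pool;

  // burn-in: single ancestral population
  int burnin = t_total - t_split;
  for (int g = 0; g < burnin; ++g) {
    reproduce(anc, n_anc, n_anc, tmp, pos, rho, L, -1, 0, 0);
    anc.swap(tmp);
    mutate(anc, empty_pool, pos, used, mu, L, collisions);
    if (g % 16 == 15) {
      std::vector<HapPool*> pl = { &anc };
      sweep_idx = compact(pl, pos, sweep_idx);
    }
  }

  bool has_sweep = sweep_pos > 0;
  int n_bn = std::max(1, (int)std::lround(bottleneck_frac * n_high));

  for (int g = 1; g <= t_split; ++g) {
    int nh_this = (g <= bottleneck_gens) ? n_bn : n_high;
    const HapPool& par_low = (g == 1) ? anc : low;
    const HapPool& par_high = (g == 1) ? anc : high;
    int np_low = (g == 1) ? n_anc : (int)(low.size() / 2);
    int np_high = (g == 1) ? n_anc : (int)(high.size() / 2);
    int sel_low = sweep_target_high ? -1 : sweep_idx;
    int sel_high = sweep_target_high ? sweep_idx : -1;
    reproduce(par_low, np_low, n_low, tmp, pos, rho, L,
              sel_low, sweep_s, sweep_h);
    HapPool new_low;
    new_low.swap(tmp);
    reproduce(par_high, np_high, nh_this, tmp, pos, rho, L,
              sel_high, sweep_s, sweep_h);
    HapPool new_high;
    new_high.swap(tmp);
    if (g == 1) { anc.clear(); anc.shrink_to_fit(); }
    low.swap(new_low);
    high.swap(new_high);

    mutate(low, high, pos, used, mu, L, collisions);
    mutate(high, low, pos, used, mu, L, collisions);

    HapPool& target = sweep_target_high ? high : low;
    // introduce the beneficial mutation in the target population
    if (has_sweep && sweep_idx < 0 && g >= std::max(1, t_onset)) {
      auto it = std::find(pos.begin(), pos.end(), sweep_pos);
      if (it == pos.end()) { // position unused or previously compacted away
        used.insert(sweep_pos);
        pos.push_back(sweep_pos);
        for (auto& hp : low) hp.push_back(0);
        for (auto& hp : high) hp.push_back(0);
        sweep_idx = (int)pos.size() - 1;
      } else { // overwrite the standing variant at the target site
        sweep_idx = (int)(it - pos.begin());
        for (auto& hp : low) hp[sweep_idx] = 0;
        for (auto& hp : high) hp[sweep_idx] = 0;
      }
      target[runif_int((int)target.size())][sweep_idx] = 1;
    }
    // re-seed on loss (standard conditioning on establishment, logged)
    if (has_sweep && sweep_idx >= 0 && count_allele(target, sweep_idx) == 0) {
      if (++reseeds > max_reseed)
        stop("sweep allele lost more than max_reseed times");
      target[runif_int((int)target.size())][sweep_idx] = 1;
    }
    if (g % 16 == 15) {
      std::vector<HapPool*> pl = { &low, &high };
      sweep_idx = compact(pl, pos, sweep_idx);
    }
  }

  double sweep_freq = NA_REAL;
  if (has_sweep && sweep_idx >= 0) {
    HapPool& target = sweep_target_high ? high : low;
    if (target.size() > 0)
      sweep_freq = (double)count_allele(target, sweep_idx) / (double)target.size();
  }

  // sample individuals without replacement (lowland first, then highland)
  auto sample_ids = [&](int N, int n) {
    std::vector<int> idx(N);
    std::iota(idx.begin(), idx.end(), 0);
    for (int i = 0; i < n; ++i) {
      int j = i + runif_int(N - i);
      std::swap(idx[i], idx[j]);
    }
    idx.resize(n);
    return idx;
  };
  if (sample_low > (int)(low.size() / 2)) stop("sample_low exceeds n_low");
  if (sample_high > (int)(high.size() / 2)) stop("sample_high exceeds n_high");
  std::vector<int> il = sample_ids((int)(low.size() / 2), sample_low);
  std::vector<int> ih = sample_ids((int)(high.size() / 2), sample_high);

  size_t S = pos.size();
  size_t nhap = 2 * (size_t)(sample_low + sample_high);
  std::vector<const Hap*> rows;
  rows.reserve(nhap);
  for (int i : il) { rows.push_back(&low[2 * i]); rows.push_back(&low[2 * i + 1]); }
  for (int i : ih) { rows.push_back(&high[2 * i]); rows.push_back(&high[2 * i + 1]); }

  // keep sites segregating within the sample, ordered by position
  std::vector<size_t> ord(S);
  std::iota(ord.begin(), ord.end(), 0);
  std::sort(ord.begin(), ord.end(),
            [&](size_t a, size_t b) { return pos[a] < pos[b]; });
  std::vector<size_t> segr;
  for (size_t j : ord) {
    size_t c = 0;
    for (auto* r : rows) c += (*r)[j];
    if (c > 0 && c < nhap) segr.push_back(j);
  }

  IntegerMatrix haps((int)nhap, (int)segr.size());
  IntegerVector out_pos((int)segr.size());
  for (size_t jj = 0; jj < segr.size(); ++jj) {
    out_pos[jj] = pos[segr[jj]];
    for (size_t r = 0; r < nhap; ++r) haps((int)r, (int)jj) = (*rows[r])[segr[jj]];
  }
  bool sweep_in_out = false;
  if (has_sweep && sweep_idx >= 0)
    for (size_t jj = 0; jj < segr.size(); ++jj)
      if (out_pos[jj] == sweep_pos) sweep_in_out = true;

  return List::create(
    _["haplotypes"] = haps,
    _["positions"] = out_pos,
    _["collisions"] = (double)collisions,
    _["reseeds"] = reseeds,
    _["sweep_freq_target"] = sweep_freq,
    _["sweep_segregating_in_sample"] = sweep_in_out);
}
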