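// Forward diploid Wright-Fisher engine for a multi-kb region.
//
// Haplotypes are sorted vectors of derived-site positions (integer bp).
// Selection coefficients of segregating deleterious sites live in a hash
// map; neutral sites are not stored there. Mutation is infinite-sites on
// integer positions: positions in use are never re-drawn, and positions
// whose mutations have gone globally extinct are recycled only if the
// region begins to saturate.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <climits>
#include <vector>

using namespace Rcpp;

typedef std::vector<int> Hap;

namespace {

struct RegionCtx {
  int L;
  double mu;
  std::vector<double> bin_cum;   // cumulative crossover rate per bin
  double total_rec;
  int bin_size;
  std::vector<int> exon_start, exon_end;   // sorted, half-open
  std::vector<double> dfe_cum;             // cumulative class weights
  std::vector<double> s_lo, s_hi;
  std::unordered_map<int, double> selmap;  // position -> s (deleterious only)
  std::unordered_set<int> used;            // all positions ever mutated
};

bool in_exon(const RegionCtx &ctx, int pos) {
  if (ctx.exon_start.empty()) return false;
  // last exon starting at or before pos
  size_t i = std::upper_bound(ctx.exon_start.begin(), ctx.exon_start.end(), pos) -
             ctx.exon_start.begin();
  if (i == 0) return false;
  return pos < ctx.exon_end[i - 1];
}

// diploid fitness: multiplicative across sites, semidominant within site
double diploid_fitness(const RegionCtx &ctx, const Hap &a, const Hap &b) {
  if (ctx.selmap.empty()) return 1.0;
  double w = 1.0;
  size_t ia = 0, ib = 0;
  while (ia < a.size() || ib < b.size()) {
    int pa = ia < a.size() ? a[ia] : INT_MAX;
    int pb = ib < b.size() ? b[ib] : INT_MAX;
    if (pa == pb) {
      auto it = ctx.selmap.find(pa);
      if (it != ctx.selmap.end()) w *= std::max(0.0, 1.0 + it->second);
      ++ia; ++ib;
    } else if (pa < pb) {
      auto it = ctx.selmap.find(pa);
      if (it != ctx.selmap.end()) w *= std::max(0.0, 1.0 + 0.5 * it->second);
      ++ia;
    } else {
      auto it = ctx.selmap.find(pb);
      if (it != ctx.selmap.end()) w *= std::max(0.0, 1.0 + 0.5 * it->second);
      ++ib;
    }
  }
  return w;
}

// copy positions of src in [lo, hi) into g
void copy_segment(const Hap &src, double lo, double hi, Hap &g) {
  Hap::const_iterator it =
      std::lower_bound(src.begin(), src.end(), (int)std::ceil(lo));
  for (; it != src.end() && *it < hi; ++it) g.push_back(*it);
}

Hap meiosis(const RegionCtx &ctx, const Hap &a, const Hap &b) {
  int which = unif_rand() < 0.5 ? 0 : 1;
  int k = ctx.total_rec > 0 ? (int)R::rpois(ctx.total_rec) : 0;
  if (k == 0) return which ? b : a;
  std::vector<double> bps(k);
  for (int i = 0; i < k; ++i) {
    double u = unif_rand() * ctx.total_rec;
    size_t bin = std::upper_bound(ctx.bin_cum.begin(), ctx.bin_cum.end(), u) -
                 ctx.bin_cum.begin();
    if (bin >= ctx.bin_cum.size()) bin = ctx.bin_cum.size() - 1;
    bps[i] = (bin + unif_rand()) * ctx.bin_size;
  }
  std::sort(bps.begin(), bps.end());
  Hap g;
  g.reserve(std::max(a.size(), b.size()));
  double lo = 0.0;
  for (int i = 0; i <= k; ++i) {
    double hi = i < k ? bps[i] : (double)ctx.L;
    copy_segment(which ? b : a, lo, hi, g);
    which = 1 - which;
    lo = hi;
  }
  return g;
}

// drop globally extinct positions from `used` so they can be recycled;
// every live copy (old generation, the next generation built so far, and
// the gamete in hand) is retained
void purge_used(RegionCtx &ctx, const std::vector<std::vector<Hap>> &pops,
                const std::vector<std::vector<Hap>> &next, const Hap &g) {
  std::unordered_set<int> live;
  for (const auto &deme : pops)
    for (const auto &h : deme) live.insert(h.begin(), h.end());
  for (const auto &deme : next)
    for (const auto &h : deme) live.insert(h.begin(), h.end());
  live.insert(g.begin(), g.end());
  std::unordered_map<int, double> sel2;
  for (int pos : live) {
    auto it = ctx.selmap.find(pos);
    if (it != ctx.selmap.end()) sel2.emplace(*it);
  }
  ctx.used.swap(live);
  ctx.selmap.swap(sel2);
}

void mutate_gamete(RegionCtx &ctx, Hap &g,
                   const std::vector<std::vector<Hap>> &pops,
                   const std::vector<std::vector<Hap>> &next) {
  int k = (int)R::rpois(ctx.mu * ctx.L);
  for (int i = 0; i < k; ++i) {
    if ((double)ctx.used.size() > 0.8 * ctx.L) {
      purge_used(ctx, pops, next, g);
      if ((double)ctx.used.size() > 0.95 * ctx.L)
        stop("region saturated with segregating/fixed mutations");
    }
    int pos;
    do {
      pos = (int)(unif_rand() * ctx.L);
      if (pos >= ctx.L) pos = ctx.L - 1;
    } while (ctx.used.count(pos));
    ctx.used.insert(pos);
    if (!ctx.dfe_cum.empty() && in_exon(ctx, pos)) {
      double u = unif_rand() * ctx.dfe_cum.back();
      size_t cls = std::upper_bound(ctx.dfe_cum.begin(), ctx.dfe_cum.end(), u) -
                   ctx.dfe_cum.begin();
      if (cls >= ctx.dfe_cum.size()) cls = ctx.dfe_cum.size() - 1;
      if (cls > 0) {  // class 0 is neutral
        double s = R::runif(ctx.s_lo[cls], ctx.s_hi[cls]);
        if (s != 0.0) ctx.selmap[pos] = s;
      }
    }
    g.insert(std::lower_bound(g.begin(), g.end(), pos), pos);
  }
}

// weighted parent index from cumulative fitness
int pick_parent(const std::vector<double> &cumw) {
  if (cumw.empty()) stop("internal: sampling parent from empty deme");
  double tot = cumw.back();
  if (tot <= 0) stop("all individuals in a deme have zero fitness");
  double u = unif_rand() * tot;
  size_t i = std::upper_bound(cumw.begin(), cumw.end(), u) - cumw.begin();
  if (i >= cumw.size()) i = cumw.size() - 1;
  return (int)i;
}

}  // namespace

// [[Rcpp::export]]
List sim_region_cpp(IntegerMatrix sizes, List ancestry, int L, double mu,
                    NumericVector bin_rates, int bin_size,
                    IntegerMatrix exons, NumericVector dfe_probs,
                    NumericVector s_lo, NumericVector s_hi,
                    IntegerVector sample_counts) {
  const int Tg = sizes.nrow() - 1;
  const int K = sizes.ncol();

  RegionCtx ctx;
  ctx.L = L;
  ctx.mu = mu;
  ctx.bin_size = bin_size;
  ctx.total_rec = 0.0;
  for (int i = 0; i < bin_rates.size(); ++i) {
    ctx.total_rec += bin_rates[i] * bin_size;
    ctx.bin_cum.push_back(ctx.total_rec);
  }
  for (int i = 0; i < exons.nrow(); ++i) {
    ctx.exon_start.push_back(exons(i, 0));
    ctx.exon_end.push_back(exons(i, 1));
  }
  double acc = 0.0;
  for (int i = 0; i < dfe_probs.size(); ++i) {
    acc += dfe_probs[i];
    ctx.dfe_cum.push_back(acc);
    ctx.s_lo.push_back(s_lo[i]);
    ctx.s_hi.push_back(s_hi[i]);
  }

  // initial populations: mutation-free
  std::vector<std::vector<Hap>> pops(K);
  for (int d = 0; d < K; ++d) pops[d].assign(2 * sizes(0, d), Hap());

  std::vector<std::vector<double>> cumw(K);
  for (int t = 1; t <= Tg; ++t) {
    NumericMatrix A = ancestry[t - 1];
    // per-deme cumulative diploid fitness for parent sampling
    for (int d = 0; d < K; ++d) {
      cumw[d].clear();
      int nd = (int)pops[d].size() / 2;
      if (nd == 0) continue;
      double run = 0.0;
      for (int i = 0; i < nd; ++i) {
        run += ctx.selmap.empty()
                   ? 1.0
                   : diploid_fitness(ctx, pops[d][2 * i], pops[d][2 * i + 1]);
        cumw[d].push_back(run);
      }
    }
    std::vector<std::vector<Hap>> next(K);
    for (int d = 0; d < K; ++d) {
      int nd = sizes(t, d);
      next[d].reserve(2 * nd);
      for (int i = 0; i < nd; ++i) {
        for (int gam = 0; gam < 2; ++gam) {
          // parent deme per gamete
          double u = unif_rand();
          int src = K - 1;
          double run = 0.0;
          for (int s = 0; s < K; ++s) {
            run += A(d, s);
            if (u <= run) { src = s; break; }
          }
          int par = pick_parent(cumw[src]);
          Hap g = meiosis(ctx, pops[src][2 * par], pops[src][2 * par + 1]);
          mutate_gamete(ctx, g, pops, next);
          next[d].push_back(std::move(g));
        }
      }
    }
    pops.swap(next);
    if (t % 64 == 0) Rcpp::checkUserInterrupt();
  }

  // sample haplotypes without replacement per deme
  std::vector<const Hap *> samp;
  std::vector<int> samp_deme;
  for (int d = 0; d < K; ++d) {
    int want = sample_counts[d];
    if (want == 0) continue;
    int avail = (int)pops[d].size();
    if (want > avail) stop("sample size exceeds haplotypes in deme");
    std::vector<int> idx(avail);
    for (int i = 0; i < avail; ++i) idx[i] = i;
    for (int i = 0; i < want; ++i) {
      int j = i + (int)(unif_rand() * (avail - i));
      if (j >= avail) j = avail - 1;
      std::swap(idx[i], idx[j]);
      samp.push_back(&pops[d][idx[i]]);
      samp_deme.push_back(d + 1);
    }
  }
  const int n = (int)samp.size();

  // segregating positions in the sample
  std::unordered_map<int, int> count;
  for (const Hap *h : samp)
    for (int pos : *h) ++count[pos];
  std::vector<int> seg;
  for (const auto &kv : count)
    if (kv.second > 0 && kv.second < n) seg.push_back(kv.first);
  std::sort(seg.begin(), seg.end());
  std::unordered_map<int, int> col;
  for (size_t j = 0; j < seg.size(); ++j) col[seg[j]] = (int)j;

  IntegerMatrix alleles(n, (int)seg.size());
  for (int i = 0; i < n; ++i)
    for (int pos : *samp[i]) {
      auto it = col.find(pos);
      if (it != col.end()) alleles(i, it->second) = 1;
    }
  NumericVector positions(seg.size());
  NumericVector selcoef(seg.size());
  for (size_t j = 0; j < seg.size(); ++j) {
    positions[j] = seg[j];
    auto it = ctx.selmap.find(seg[j]);
    selcoef[j] = it == ctx.selmap.end() ? 0.0 : it->second;
  }
  return List::create(_["positions"] = positions, _["alleles"] = alleles,
                      _["deme"] = samp_deme, _["selcoef"] = selcoef);
}

// [[Rcpp::export]]
IntegerVector draw_crossover_counts_cpp(NumericVector bin_rates, int bin_size,
                                        int n) {
  double total = 0.0;
  for (int i = 0; i < bin_rates.size(); ++i) total += bin_rates[i] * bin_size;
  IntegerVector out(n);
  for (int i = 0; i < n; ++i) out[i] = (int)R::rpois(total);
  return out;
}
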