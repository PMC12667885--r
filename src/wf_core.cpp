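#include <Rcpp.h>
#include <vector>
#include <cstdint>
#include <cmath>

using namespace Rcpp;

// Fair coin flips drawn in batches of 32 bits from R's uniform generator, so
// Mendelian segregation stays on R's RNG stream (reproducible via set.seed)
// without one unif_rand() call per heterozygous transmission.
struct CoinCache {
  uint32_t bits = 0;
  int n = 0;
  inline int bit() {
    if (n == 0) {
      bits = static_cast<uint32_t>(unif_rand() * 4294967296.0);
      n = 32;
    }
    int b = static_cast<int>(bits & 1u);
    bits >>= 1;
    --n;
    return b;
  }
};

// Segregating sites in compressed sparse form: per site, the list of carrier
// individuals and their copy number (1 or 2). Monomorphic columns never
// exist: fixed sites are folded into the phenotype offset, lost sites are
// dropped. Cost per generation scales with the number of segregating copies,
// not sites x individuals.
struct SiteTable {
  std::vector<double> effect;    // one per site
  std::vector<int> start;        // CSR offsets, size nsites + 1
  std::vector<int> carrier;      // individual index per entry
  std::vector<uint8_t> count;    // copy number per entry (1 or 2)
  SiteTable() { start.push_back(0); }
  int nsites() const { return static_cast<int>(effect.size()); }
  void clear() {
    effect.clear(); carrier.clear(); count.clear();
    start.assign(1, 0);
  }
  void add_entry(int ind, uint8_t c) {
    carrier.push_back(ind);
    count.push_back(c);
  }
  void close_site(double a) {
    effect.push_back(a);
    start.push_back(static_cast<int>(carrier.size()));
  }
};

struct Population {
  int n;                   // diploid census size
  SiteTable sites;
  double offset;           // phenotypic contribution of fixed sites
  std::vector<double> g;   // genetic value per individual, kept in sync
  Population(int n_) : n(n_), offset(0.0), g(n_, 0.0) {}
  void recompute_g() {
    std::fill(g.begin(), g.end(), offset);
    for (int s = 0; s < sites.nsites(); ++s) {
      const double a = sites.effect[s];
      for (int k = sites.start[s]; k < sites.start[s + 1]; ++k) {
        g[sites.carrier[k]] += sites.count[k] * a;
      }
    }
  }
};

// fitness-proportional parent draw via binary search on the cumulative sum
static inline int sample_parent(const std::vector<double> &cumw) {
  double u = unif_rand() * cumw.back();
  int lo = 0, hi = static_cast<int>(cumw.size()) - 1;
  while (lo < hi) {
    int mid = (lo + hi) / 2;
    if (cumw[mid] < u) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// Scratch space reused across generations.
struct Workspace {
  std::vector<double> cumw, gnew;
  std::vector<int> par1, par2;
  std::vector<int> cstart, cfill, cuse;  // children-of-parent CSR (2n uses)
  std::vector<uint8_t> acc;              // per-offspring copies, one site
  std::vector<int> touched;              // compaction buffer; one slack slot
                                         // because the write is unconditional
  SiteTable next;
  Workspace(int n) : cumw(n), gnew(n), par1(n), par2(n),
                     cstart(n + 1), cfill(n), cuse(2 * n), acc(n, 0),
                     touched(n + 1) {}
};

// Advance one non-overlapping Wright-Fisher generation: Gaussian stabilizing
// selection on the phenotype, fitness-weighted multinomial parent sampling
// (monoecious, selfing allowed), independent Mendelian transmission per site
// (free recombination), infinite-sites mutation with a Poisson total of
// 2 n u new mutations assigned to uniformly chosen gametes (equivalent to
// Poisson(u) per gamete), then folding of fixed sites into the offset.
// Offspring genetic values are accumulated during transmission, so pop.g is
// always current.
static void step_generation(Population &pop, double u, double sd_m, double vs,
                            double ve, double optimum, CoinCache &coin,
                            Workspace &ws) {
  const int n = pop.n;

  bool any_pos = false;
  const double sd_e = ve > 0 ? std::sqrt(ve) : 0.0;
  double accw = 0.0;
  for (int i = 0; i < n; ++i) {
    double p = pop.g[i];
    if (ve > 0) p += norm_rand() * sd_e;
    double wi = R_FINITE(vs)
      ? std::exp(-(p - optimum) * (p - optimum) / (2.0 * vs)) : 1.0;
    if (wi > 0) any_pos = true;
    accw += wi;
    ws.cumw[i] = accw;
  }
  if (!any_pos)
    stop("all fitnesses underflowed to zero; use a larger vs or smaller vm");

  for (int i = 0; i < n; ++i) {
    ws.par1[i] = sample_parent(ws.cumw);
    ws.par2[i] = sample_parent(ws.cumw);
  }

  // children-of-parent lists (counting sort over the 2n parent uses); each
  // use is one gamete owed to offspring `i`
  std::fill(ws.cstart.begin(), ws.cstart.end(), 0);
  for (int i = 0; i < n; ++i) {
    ++ws.cstart[ws.par1[i] + 1];
    ++ws.cstart[ws.par2[i] + 1];
  }
  for (int p = 0; p < n; ++p) ws.cstart[p + 1] += ws.cstart[p];
  std::copy(ws.cstart.begin(), ws.cstart.end() - 1, ws.cfill.begin());
  for (int i = 0; i < n; ++i) {
    ws.cuse[ws.cfill[ws.par1[i]]++] = i;
    ws.cuse[ws.cfill[ws.par2[i]]++] = i;
  }

  // transmit each segregating site from its carriers to their offspring,
  // accumulating offspring genetic values as we go
  std::fill(ws.gnew.begin(), ws.gnew.end(), pop.offset);
  SiteTable &next = ws.next;
  next.clear();
  const SiteTable &S = pop.sites;
  for (int s = 0; s < S.nsites(); ++s) {
    const double a = S.effect[s];
    int total = 0;
    int tpos = 0;
    // branchless transmission: one fair bit per gamete (homozygous carriers
    // force it to 1), compaction instead of conditional pushes
    for (int k = S.start[s]; k < S.start[s + 1]; ++k) {
      const int p = S.carrier[k];
      const int ishom = S.count[k] == 2;
      for (int c = ws.cstart[p]; c < ws.cstart[p + 1]; ++c) {
        const int b = ishom | coin.bit();
        const int child = ws.cuse[c];
        const uint8_t prev = ws.acc[child];
        ws.touched[tpos] = child;
        tpos += b & static_cast<int>(prev == 0);
        ws.acc[child] = prev + static_cast<uint8_t>(b);
        total += b;
      }
    }
    if (total == 2 * n) {
      pop.offset += 2.0 * a;   // fixed; every child received two copies
      for (int i = 0; i < n; ++i) ws.gnew[i] += 2.0 * a;
      for (int t = 0; t < tpos; ++t) ws.acc[ws.touched[t]] = 0;
    } else if (total > 0) {
      for (int t = 0; t < tpos; ++t) {
        const int child = ws.touched[t];
        next.add_entry(child, ws.acc[child]);
        ws.gnew[child] += ws.acc[child] * a;
        ws.acc[child] = 0;
      }
      next.close_site(a);
    }
  }

  if (u > 0) {
    int k = static_cast<int>(R::rpois(2.0 * n * u));
    for (int m = 0; m < k; ++m) {
      int gam = static_cast<int>(unif_rand() * 2 * n);
      if (gam == 2 * n) gam = 2 * n - 1;
      const double a = norm_rand() * sd_m;
      next.add_entry(gam / 2, 1);
      next.close_site(a);
      ws.gnew[gam / 2] += a;
    }
  }

  std::swap(pop.sites, next);
  std::swap(pop.g, ws.gnew);
}

// Run one replicate: burn-in, then record mean fitness, genetic variance and
// mean genetic value every record_every generations, n_samples times.
// Optionally start from a supplied genotype matrix (individuals x sites) and
// stop early once no site segregates (used for absorption experiments).
// [[Rcpp::export]]
List wf_run_cpp(int n, double u, double vm, double vs, double ve,
                double optimum, int burn_in, int record_every, int n_samples,
                Nullable<IntegerMatrix> init_genotypes = R_NilValue,
                Nullable<NumericVector> init_effects = R_NilValue,
                double init_offset = 0.0, bool stop_when_monomorphic = false) {
  if (n < 2) stop("n must be >= 2");
  Population pop(n);
  pop.offset = init_offset;
  if (init_genotypes.isNotNull()) {
    IntegerMatrix gm(init_genotypes);
    NumericVector ef = init_effects.isNotNull()
      ? NumericVector(init_effects) : NumericVector(gm.ncol());
    if (gm.nrow() != n || ef.size() != gm.ncol())
      stop("init_genotypes must be n x length(init_effects)");
    for (int j = 0; j < gm.ncol(); ++j) {
      int total = 0;
      for (int i = 0; i < n; ++i) {
        int c = gm(i, j);
        if (c < 0 || c > 2) stop("genotype counts must be 0, 1 or 2");
        total += c;
      }
      if (total == 0) continue;
      if (total == 2 * n) { pop.offset += 2.0 * ef[j]; continue; }
      for (int i = 0; i < n; ++i) {
        if (gm(i, j) > 0)
          pop.sites.add_entry(i, static_cast<uint8_t>(gm(i, j)));
      }
      pop.sites.close_site(ef[j]);
    }
  }
  pop.recompute_g();

  const double sd_m = std::sqrt(vm);
  CoinCache coin;
  Workspace ws(n);
  NumericVector mean_fitness(n_samples), vg(n_samples), pbar(n_samples);
  IntegerVector gens(n_samples);
  int generation = 0;

  for (int t = 0; t < burn_in; ++t) {
    step_generation(pop, u, sd_m, vs, ve, optimum, coin, ws);
    ++generation;
    if (stop_when_monomorphic && pop.sites.nsites() == 0) break;
  }

  int recorded = 0;
  if (!(stop_when_monomorphic && pop.sites.nsites() == 0)) {
    for (int s = 0; s < n_samples; ++s) {
      // census of the current generation
      double sum = 0.0, sumsq = 0.0, wsum = 0.0;
      for (int i = 0; i < n; ++i) {
        sum += pop.g[i];
        sumsq += pop.g[i] * pop.g[i];
        double p = pop.g[i];
        if (ve > 0) p += norm_rand() * std::sqrt(ve);
        wsum += R_FINITE(vs)
          ? std::exp(-(p - optimum) * (p - optimum) / (2.0 * vs)) : 1.0;
      }
      double m = sum / n;
      pbar[s] = m;
      vg[s] = sumsq / n - m * m;
      mean_fitness[s] = wsum / n;
      gens[s] = generation;
      ++recorded;
      if (s == n_samples - 1) break;
      for (int t = 0; t < record_every; ++t) {
        step_generation(pop, u, sd_m, vs, ve, optimum, coin, ws);
        ++generation;
      }
    }
  }

  return List::create(
    _["mean_fitness"] = mean_fitness, _["vg"] = vg, _["pbar"] = pbar,
    _["generation"] = gens, _["n_recorded"] = recorded,
    _["n_segregating"] = pop.sites.nsites(),
    _["offset"] = pop.offset, _["final_generation"] = generation);
}
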