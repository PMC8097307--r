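// Simulation and detection engines.
//
// Three compiled workhorses:
//  * a per-site structured-coalescent simulator (discrete generations,
//    size epochs, splits, symmetric migration) used for genotype panels,
//    allele counts and joint SFS;
//  * a pairwise SMC walk generating identity-by-descent segment truth
//    under a piecewise-constant size history;
//  * a hash seed-and-extend IBD segment detector for phased haplotypes.
//
// All randomness comes from R's RNG so set.seed() governs every draw.

#include <Rcpp.h>
#include <vector>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

namespace {

// ---------------------------------------------------------------------------
// structured coalescent
// ---------------------------------------------------------------------------

struct DemeEpochs {
  std::vector<double> start, end, gc;  // gc = gene copies (2N diploid)
  int cur = 0;
  double gene_copies(double t) {
    while (cur + 1 < (int)start.size() && t >= end[cur]) ++cur;
    return gc[cur];
  }
  void reset() { cur = 0; }
};

struct Split { double time; int derived, ancestral; };
struct MigWin { int a, b; double rate, start, end; };

struct Engine {
  int n_demes;
  std::vector<DemeEpochs> eps;
  std::vector<Split> splits;
  std::vector<MigWin> migs;
  std::vector<double> boundaries;        // sorted times where hazards change
  std::vector<std::vector<int>> members; // lineage node ids per deme
  // tree arrays (size 2n-1)
  std::vector<double> ntime, ptime;
  std::vector<int> child1, child2;
  std::vector<int> leaf_deme;            // sampled-deme index per leaf
  int n_leaves = 0;

  void setup(const DataFrame& ep, const DataFrame& sp, const DataFrame& mg,
             const IntegerVector& sample_demes,
             const IntegerVector& sample_sizes) {
    IntegerVector ed = ep["deme"];
    NumericVector es = ep["start"], ee = ep["end"], eg = ep["gene_copies"];
    n_demes = 0;
    for (int i = 0; i < ed.size(); ++i) n_demes = std::max(n_demes, ed[i] + 1);
    eps.assign(n_demes, DemeEpochs());
    for (int i = 0; i < ed.size(); ++i) {
      eps[ed[i]].start.push_back(es[i]);
      eps[ed[i]].end.push_back(ee[i]);
      eps[ed[i]].gc.push_back(eg[i]);
      if (R_finite(es[i]) && es[i] > 0) boundaries.push_back(es[i]);
      if (R_finite(ee[i])) boundaries.push_back(ee[i]);
    }
    NumericVector st = sp["time"];
    IntegerVector sd = sp["derived"], sa = sp["ancestral"];
    for (int i = 0; i < st.size(); ++i) {
      splits.push_back({st[i], sd[i], sa[i]});
      boundaries.push_back(st[i]);
    }
    std::sort(splits.begin(), splits.end(),
              [](const Split& x, const Split& y) { return x.time < y.time; });
    if (mg.nrows() > 0) {
      IntegerVector ma = mg["a"], mb = mg["b"];
      NumericVector mr = mg["rate"], ms = mg["start"], me = mg["end"];
      for (int i = 0; i < ma.size(); ++i) {
        migs.push_back({ma[i], mb[i], mr[i], ms[i], me[i]});
        if (ms[i] > 0) boundaries.push_back(ms[i]);
        if (R_finite(me[i])) boundaries.push_back(me[i]);
      }
    }
    std::sort(boundaries.begin(), boundaries.end());
    boundaries.erase(std::unique(boundaries.begin(), boundaries.end()),
                     boundaries.end());
    members.assign(n_demes, {});
    n_leaves = 0;
    for (int i = 0; i < sample_sizes.size(); ++i) n_leaves += 2 * sample_sizes[i];
    leaf_deme.resize(n_leaves);
    int id = 0;
    for (int i = 0; i < sample_sizes.size(); ++i)
      for (int j = 0; j < 2 * sample_sizes[i]; ++j) leaf_deme[id++] = i;
    int nn = 2 * n_leaves - 1;
    ntime.resize(nn); ptime.resize(nn);
    child1.resize(nn); child2.resize(nn);
    sample_deme_ids.assign(sample_demes.begin(), sample_demes.end());
  }

  std::vector<int> sample_deme_ids;

  void merge_random_pair(int d, double t, int& next_node, int& total_k) {
    std::vector<int>& m = members[d];
    int k = (int)m.size();
    int i = (int)(unif_rand() * k);
    int j = (int)(unif_rand() * (k - 1));
    if (j >= i) ++j;
    int a = m[i], b = m[j];
    int nn = next_node++;
    ntime[nn] = t; child1[nn] = a; child2[nn] = b;
    ptime[a] = t; ptime[b] = t;
    // replace i with new node, remove j (swap with back)
    m[i] = nn;
    m[j] = m.back(); m.pop_back();
    --total_k;
  }

  // simulate one genealogy; returns root node id
  int simulate_tree() {
    for (auto& e : eps) e.reset();
    for (auto& m : members) m.clear();
    for (int i = 0; i < n_leaves; ++i) {
      members[sample_deme_ids[leaf_deme[i]]].push_back(i);
      ntime[i] = 0.0; child1[i] = -1; child2[i] = -1;
    }
    int total_k = n_leaves;
    int next_node = n_leaves;
    double t = 0.0;
    size_t sp_idx = 0, bd_idx = 0;
    const double JUMP = 0.1;
    long guard = 0;
    while (total_k > 1) {
      if (++guard > 100000000L) stop("coalescent simulation did not terminate");
      // process due splits
      while (sp_idx < splits.size() && splits[sp_idx].time <= t) {
        const Split& s = splits[sp_idx];
        std::vector<int>& from = members[s.derived];
        std::vector<int>& to = members[s.ancestral];
        to.insert(to.end(), from.begin(), from.end());
        from.clear();
        ++sp_idx;
      }
      while (bd_idx < boundaries.size() && boundaries[bd_idx] <= t) ++bd_idx;
      double tb = bd_idx < boundaries.size() ? boundaries[bd_idx] : R_PosInf;
      // hazards
      double lam_tot = 0.0, log_p0 = 0.0;
      double lam_c[64];
      int live[64], n_live = 0;
      for (int d = 0; d < n_demes; ++d) {
        int k = (int)members[d].size();
        if (k >= 2) {
          double q = 1.0 / eps[d].gene_copies(t);
          double C = 0.5 * k * (k - 1);
          lam_c[n_live] = C * q;
          live[n_live++] = d;
          lam_tot += C * q;
          log_p0 += C * log1p(-q);
        }
      }
      int n_mig = 0;
      double lam_m[128], mig_rate[128]; int mig_from[128], mig_to[128];
      for (const MigWin& w : migs) {
        if (t >= w.start && t < w.end) {
          int ka = (int)members[w.a].size(), kb = (int)members[w.b].size();
          if (ka > 0 && kb + ka > 1) { // movement only matters with >1 lineage total
            lam_m[n_mig] = ka * w.rate; mig_rate[n_mig] = w.rate;
            mig_from[n_mig] = w.a; mig_to[n_mig] = w.b;
            lam_tot += lam_m[n_mig]; log_p0 += ka * log1p(-w.rate); ++n_mig;
          }
          if (kb > 0 && ka + kb > 1) {
            lam_m[n_mig] = kb * w.rate; mig_rate[n_mig] = w.rate;
            mig_from[n_mig] = w.b; mig_to[n_mig] = w.a;
            lam_tot += lam_m[n_mig]; log_p0 += kb * log1p(-w.rate); ++n_mig;
          }
        }
      }
      if (lam_tot <= 0.0) {
        if (!R_finite(tb)) stop("no possible events remain with >1 lineage (invalid model?)");
        t = tb;
        continue;
      }
      if (lam_tot < JUMP) {
        // geometric jump to first event generation (at most one event/gen regime)
        double p = -expm1(log_p0);
        double G = 1.0 + R::rgeom(p);
        if (t + G <= tb) {
          t += G;
          // pick event proportional to hazards
          double u = unif_rand() * lam_tot;
          bool done = false;
          for (int i = 0; i < n_live; ++i) {
            if (u < lam_c[i]) { merge_random_pair(live[i], t, next_node, total_k); done = true; break; }
            u -= lam_c[i];
          }
          if (!done) {
            for (int i = 0; i < n_mig; ++i) {
              if ((u < lam_m[i] || i == n_mig - 1) && !members[mig_from[i]].empty()) {
                std::vector<int>& from = members[mig_from[i]];
                int j = (int)(unif_rand() * from.size());
                members[mig_to[i]].push_back(from[j]);
                from[j] = from.back(); from.pop_back();
                break;
              }
              u -= lam_m[i];
            }
          }
        } else {
          t = tb;
        }
      } else {
        // step a single generation, allowing multiple events
        double tp = t + 1.0;
        for (int i = 0; i < n_live; ++i) {
          int d = live[i];
          int k = (int)members[d].size();
          if (k < 2) continue;
          double q = 1.0 / eps[d].gene_copies(t);
          if (lam_c[i] < 0.1) {
            double p = -expm1(0.5 * k * (k - 1) * log1p(-q));
            if (unif_rand() < p) merge_random_pair(d, tp, next_node, total_k);
          } else {
            int nm = (int)R::rbinom(0.5 * k * (k - 1), q);
            for (int r = 0; r < nm && (int)members[d].size() >= 2; ++r)
              merge_random_pair(d, tp, next_node, total_k);
          }
        }
        for (int i = 0; i < n_mig; ++i) {
          std::vector<int>& from = members[mig_from[i]];
          int k = (int)from.size();
          if (k == 0) continue;
          double rate = mig_rate[i];
          int nmv;
          if (k * rate < 0.01) nmv = (unif_rand() < k * rate) ? 1 : 0;
          else nmv = (int)R::rbinom((double)k, rate);
          for (int r = 0; r < nmv && !from.empty(); ++r) {
            int j = (int)(unif_rand() * from.size());
            members[mig_to[i]].push_back(from[j]);
            from[j] = from.back(); from.pop_back();
          }
        }
        t = tp;
      }
    }
    return next_node - 1;
  }

  double total_branch_length(int root) const {
    double s = 0.0;
    for (int v = 0; v < root; ++v) s += ptime[v] - ntime[v];
    return s;
  }

  // choose a branch uniformly on total length; return node id (never root)
  int mutate_branch(int root) const {
    double T = total_branch_length(root);
    double u = unif_rand() * T, acc = 0.0;
    for (int v = 0; v < root; ++v) {
      acc += ptime[v] - ntime[v];
      if (u < acc) return v;
    }
    return root - 1;
  }

  // count leaves below node per sampled deme; optionally record leaf ids
  void leaves_below(int v, std::vector<int>& counts,
                    std::vector<int>* leaf_ids) const {
    static thread_local std::vector<int> stack;
    stack.clear(); stack.push_back(v);
    while (!stack.empty()) {
      int x = stack.back(); stack.pop_back();
      if (child1[x] < 0) {
        ++counts[leaf_deme[x]];
        if (leaf_ids) leaf_ids->push_back(x);
      } else {
        stack.push_back(child1[x]);
        stack.push_back(child2[x]);
      }
    }
  }
};

}  // namespace

// Simulate independent-site genealogies and place mutations.
//
// mode 0: one mutation per tree; returns per-site derived counts per sampled
//         deme plus per-site TMRCA (root time).
// mode 1: as 0 but also fills a haplotype 0/1 matrix (n_hap x n_sites).
// mode 2: Poisson mutation mode: per tree, N_mut ~ Poisson(mu_locus * L_tree)
//         mutations dropped on the same tree; only counts are returned and the
//         number of emitted sites is random (trees may emit none).
// weight_mode 1 samples each site's genealogy length-weighted (the
// distribution of the tree at a random segregating site in the theta -> 0
// limit), via rejection against an adaptive envelope calibrated on 200
// pilot genealogies; weight_mode 0 uses plain genealogy draws.
// [[Rcpp::export]]
List cpp_simulate_sites(DataFrame epochs, DataFrame splits, DataFrame migrations,
                        IntegerVector sample_demes, IntegerVector sample_sizes,
                        int n_sites, int mode, double mu_locus,
                        int weight_mode) {
  Engine eng;
  eng.setup(epochs, splits, migrations, sample_demes, sample_sizes);
  if (eng.n_leaves < 2) stop("at least 2 haplotypes are required (no coalescence possible)");
  int n_sd = sample_sizes.size();
  std::vector<int> counts(n_sd);
  double M = 0.0;  // rejection envelope for length-weighted sampling
  if (weight_mode == 1 && mode != 2) {
    const int n_pilot = 200;
    double sum = 0.0, mx = 0.0;
    for (int i = 0; i < n_pilot; ++i) {
      int root = eng.simulate_tree();
      double L = eng.total_branch_length(root);
      sum += L; if (L > mx) mx = L;
    }
    M = std::max(2.5 * sum / n_pilot, 2.0 * mx);
  }

  if (mode == 2) {
    std::vector<std::vector<int>> rows;
    std::vector<double> tmrcas;
    for (int s = 0; s < n_sites; ++s) {  // n_sites = number of trees here
      int root = eng.simulate_tree();
      double L = eng.total_branch_length(root);
      int nm = (int)R::rpois(mu_locus * L);
      for (int m = 0; m < nm; ++m) {
        int v = eng.mutate_branch(root);
        std::fill(counts.begin(), counts.end(), 0);
        eng.leaves_below(v, counts, nullptr);
        rows.push_back(counts);
        tmrcas.push_back(eng.ntime[root]);
      }
    }
    IntegerMatrix cm(rows.size(), n_sd);
    for (size_t i = 0; i < rows.size(); ++i)
      for (int j = 0; j < n_sd; ++j) cm(i, j) = rows[i][j];
    return List::create(_["counts"] = cm,
                        _["tmrca"] = NumericVector(tmrcas.begin(), tmrcas.end()));
  }

  IntegerMatrix cm(n_sites, n_sd);
  NumericVector tm(n_sites);
  IntegerMatrix geno = (mode == 1) ? IntegerMatrix(eng.n_leaves, n_sites)
                                   : IntegerMatrix(0, 0);
  std::vector<int> leaf_ids;
  for (int s = 0; s < n_sites; ++s) {
    int root = eng.simulate_tree();
    if (weight_mode == 1) {
      // accept genealogy with probability proportional to its length
      while (true) {
        double L = eng.total_branch_length(root);
        if (L >= M || unif_rand() < L / M) break;
        root = eng.simulate_tree();
      }
    }
    tm[s] = eng.ntime[root];
    int v = eng.mutate_branch(root);
    std::fill(counts.begin(), counts.end(), 0);
    if (mode == 1) {
      leaf_ids.clear();
      eng.leaves_below(v, counts, &leaf_ids);
      for (int id : leaf_ids) geno(id, s) = 1;
    } else {
      eng.leaves_below(v, counts, nullptr);
    }
    for (int j = 0; j < n_sd; ++j) cm(s, j) = counts[j];
  }
  List out = List::create(_["counts"] = cm, _["tmrca"] = tm);
  if (mode == 1) out["geno"] = geno;
  return out;
}

// ---------------------------------------------------------------------------
// pairwise SMC identity-by-descent truth
// ---------------------------------------------------------------------------

namespace {

// piecewise-constant per-generation coalescence probability; samples the
// generation of coalescence for a lineage detached at integer level u.
struct CoalSampler {
  std::vector<double> pstart;  // piece start generations (pstart[0] = 1)
  std::vector<double> h;       // per-generation hazard -log(1-q) per piece
  std::vector<double> cumH;    // cumulative hazard at piece starts
  void setup(const NumericVector& starts, const NumericVector& q) {
    int n = starts.size();
    pstart.assign(starts.begin(), starts.end());
    h.resize(n); cumH.assign(n, 0.0);
    for (int i = 0; i < n; ++i) h[i] = -log1p(-q[i]);
    for (int i = 1; i < n; ++i)
      cumH[i] = cumH[i - 1] + (pstart[i] - pstart[i - 1]) * h[i - 1];
  }
  double cum_at(double g) const {  // cumulative hazard of generations [1, g]
    if (g < pstart[0]) return 0.0;
    int lo = 0, hi = (int)pstart.size() - 1;
    while (lo < hi) {  // find last piece with pstart <= g
      int mid = (lo + hi + 1) / 2;
      if (pstart[mid] <= g) lo = mid; else hi = mid - 1;
    }
    return cumH[lo] + (g - pstart[lo] + 1.0) * h[lo];
  }
  // smallest integer g >= g0 with cum(g) - cum(g0-1) >= E
  double sample(double g0) const {
    double E = R::rexp(1.0);
    double target = E + cum_at(g0 - 1.0);
    int n = (int)pstart.size();
    int lo = 0, hi = n - 1;
    while (lo < hi) {  // first piece whose end-cum >= target
      int mid = (lo + hi) / 2;
      double endcum = (mid + 1 < n) ? cumH[mid + 1] : R_PosInf;
      if (endcum >= target) hi = mid; else lo = mid + 1;
    }
    double g = pstart[lo] + ceil((target - cumH[lo]) / h[lo]) - 1.0;
    if (g < g0) g = g0;
    if (g < pstart[lo]) g = pstart[lo];
    return g;
  }
};

}  // namespace

// SMC walk along a chromosome for n_pairs haplotype pairs.
// starts/q define the piecewise-constant coalescence probability per
// generation (starts[0] must be 1; last piece extends to infinity).
// Returns tiling segments (start/end in cM, TMRCA in generations), keeping
// only segments of length >= min_emit_cM.
// [[Rcpp::export]]
DataFrame cpp_smc_ibd(NumericVector starts, NumericVector q,
                      double chrom_len_cM, int n_pairs, double min_emit_cM) {
  CoalSampler cs;
  cs.setup(starts, q);
  std::vector<int> pair_out;
  std::vector<double> s_out, e_out, t_out;
  const double Lm = chrom_len_cM / 100.0;  // Morgans
  for (int p = 0; p < n_pairs; ++p) {
    if (chrom_len_cM <= 0) break;
    double pos = 0.0, seg_start = 0.0;
    double T = cs.sample(1.0);
    long guard = 0;
    while (true) {
      if (++guard > 200000000L) stop("SMC walk did not terminate");
      double d = R::rexp(1.0) / (2.0 * T);  // Morgans to next recombination
      double nxt = pos + d;
      if (nxt >= Lm) {
        if ((Lm - seg_start) * 100.0 >= min_emit_cM) {
          pair_out.push_back(p + 1);
          s_out.push_back(seg_start * 100.0);
          e_out.push_back(chrom_len_cM);
          t_out.push_back(T);
        }
        break;
      }
      // recombination: detach uniformly below T, re-coalesce
      double u = floor(unif_rand() * T);
      double Tn = cs.sample(u + 1.0);
      if (Tn != T) {
        if ((nxt - seg_start) * 100.0 >= min_emit_cM) {
          pair_out.push_back(p + 1);
          s_out.push_back(seg_start * 100.0);
          e_out.push_back(nxt * 100.0);
          t_out.push_back(T);
        }
        seg_start = nxt;
        T = Tn;
      }
      pos = nxt;
    }
  }
  return DataFrame::create(_["pair"] = pair_out, _["start_cM"] = s_out,
                           _["end_cM"] = e_out, _["tmrca"] = t_out);
}

// ---------------------------------------------------------------------------
// seed-and-extend IBD detection
// ---------------------------------------------------------------------------

// haps: n_hap x n_sites 0/1 matrix; cm: genetic positions per site.
// Exact-match words of seed_len sites seed candidate pairs; candidate pairs
// are scanned for dense-mismatch breakpoints (> max_mismatch mismatches
// within any seed_len-site window); intervals between breakpoints that
// contain a seeded word and span >= min_cM are reported.
// [[Rcpp::export]]
DataFrame cpp_detect_ibd(IntegerMatrix haps, NumericVector cm,
                         int seed_len, int max_mismatch, double min_cM,
                         int break_window) {
  int H = haps.nrow(), S = haps.ncol();
  if (H < 2 || S < seed_len)
    return DataFrame::create(_["hap1"] = IntegerVector(0),
                             _["hap2"] = IntegerVector(0),
                             _["start_site"] = IntegerVector(0),
                             _["end_site"] = IntegerVector(0),
                             _["n_discordant"] = IntegerVector(0));
  // pack haplotypes into 64-bit blocks for fast XOR scans
  int nblk = (S + 63) / 64;
  std::vector<uint64_t> packed((size_t)H * nblk, 0);
  for (int i = 0; i < H; ++i)
    for (int s = 0; s < S; ++s)
      if (haps(i, s)) packed[(size_t)i * nblk + (s >> 6)] |= (uint64_t)1 << (s & 63);

  int n_words = S / seed_len;
  // candidate pairs and their seeded words
  std::unordered_map<uint64_t, std::vector<int>> word_groups;
  std::unordered_map<uint64_t, std::vector<int>> pair_words;  // key -> word idx
  std::vector<uint64_t> pair_keys;
  for (int w = 0; w < n_words; ++w) {
    word_groups.clear();
    int s0 = w * seed_len;
    for (int i = 0; i < H; ++i) {
      uint64_t key = 1469598103934665603ULL;  // FNV-1a over the word's bits
      for (int s = s0; s < s0 + seed_len; ++s) {
        key ^= (uint64_t)haps(i, s);
        key *= 1099511628211ULL;
      }
      word_groups[key].push_back(i);
    }
    for (auto& kv : word_groups) {
      std::vector<int>& g = kv.second;
      if (g.size() < 2) continue;
      for (size_t a = 0; a < g.size(); ++a)
        for (size_t b = a + 1; b < g.size(); ++b) {
          uint64_t pk = ((uint64_t)g[a] << 32) | (uint32_t)g[b];
          auto it = pair_words.find(pk);
          if (it == pair_words.end()) {
            pair_words[pk] = {w};
            pair_keys.push_back(pk);
          } else it->second.push_back(w);
        }
    }
  }

  std::vector<int> h1o, h2o, sso, seo, ndo;
  std::vector<int> mism;
  for (uint64_t pk : pair_keys) {
    int i = (int)(pk >> 32), j = (int)(uint32_t)pk;
    const std::vector<int>& words = pair_words[pk];
    mism.clear();
    const uint64_t* pi = &packed[(size_t)i * nblk];
    const uint64_t* pj = &packed[(size_t)j * nblk];
    for (int b = 0; b < nblk; ++b) {
      uint64_t x = pi[b] ^ pj[b];
      while (x) {
        int bit = __builtin_ctzll(x);
        int s = b * 64 + bit;
        if (s < S) mism.push_back(s);
        x &= x - 1;
      }
    }
    int M = (int)mism.size();
    // mark mismatches that belong to a dense cluster (break sites);
    // the cluster window is tighter than the seed so an isolated discordant
    // site near a segment boundary is not absorbed into the boundary's
    // cluster (which would clip the segment end)
    std::vector<char> brk(M, 0);
    for (int a = 0; a + max_mismatch < M; ++a)
      if (mism[a + max_mismatch] - mism[a] < break_window)
        for (int b = a; b <= a + max_mismatch; ++b) brk[b] = 1;
    // candidate intervals between break sites (and chromosome ends)
    std::vector<int> bounds;  // break site indices into mism
    for (int a = 0; a < M; ++a) if (brk[a]) bounds.push_back(a);
    int prev_end = 0;  // interval start site
    size_t bi = 0;
    while (true) {
      int start_site = prev_end;
      int end_site;  // exclusive
      if (bi < bounds.size()) end_site = mism[bounds[bi]];
      else end_site = S;
      if (end_site - start_site >= seed_len) {
        // must contain a seeded word
        bool has_seed = false;
        for (int w : words)
          if (w * seed_len >= start_site && (w + 1) * seed_len <= end_site) {
            has_seed = true; break;
          }
        if (has_seed) {
          double len = cm[end_site - 1] - cm[start_site];
          if (len >= min_cM) {
            int nd = 0;
            for (int a = 0; a < M; ++a)
              if (!brk[a] && mism[a] >= start_site && mism[a] < end_site) ++nd;
            h1o.push_back(i + 1); h2o.push_back(j + 1);
            sso.push_back(start_site + 1); seo.push_back(end_site);
            ndo.push_back(nd);
          }
        }
      }
      if (bi >= bounds.size()) break;
      prev_end = mism[bounds[bi]] + 1;
      ++bi;
    }
  }
  return DataFrame::create(_["hap1"] = h1o, _["hap2"] = h2o,
                           _["start_site"] = sso, _["end_site"] = seo,
                           _["n_discordant"] = ndo);
}
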