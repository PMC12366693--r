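// Forward lattice demography and conditioned backward coalescent.
//
// The forward kernel records, per generation, everything the backward pass
// needs to reconstruct lineage movement exactly: post-regulation sizes,
// post-admixture (pre-migration) sizes, resident counts, stepping-stone
// immigrant counts by source direction, long-distance dispersal events and
// HG->FA admixture transfers. Backward source probabilities use these
// recorded counts, so forward and backward are consistent by construction.
//
// All randomness goes through R's RNG (RNGScope), so set.seed() in R makes
// both kernels deterministic.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int DX[4] = {-1, 1, 0, 0};  // W E S N (source offset)
static const int DY[4] = {0, 0, -1, 1};
static inline int opp(int k) { return k ^ 1; }  // 0<->1, 2<->3

static inline long long lv_step(long long n, long long other, double r,
                                double K, double alpha) {
  if (n <= 0) return 0;
  double nn = (double)n;
  double next = nn + r * nn * (1.0 - (nn + alpha * (double)other) / K);
  long long out = (long long)std::llround(next);
  return out < 0 ? 0 : out;
}

// [[Rcpp::export]]
List cpp_forward_sim(int n_cols, int n_rows, LogicalVector land, int T,
                     double K_hg, double r_hg, double m_hg, double p_ldd_hg,
                     double K_fa, double r_fa, double m_fa, double p_ldd_fa,
                     NumericVector alpha, NumericVector gamma_max,
                     bool ramp, double t_inc, int hg_origin, int fa_origin,
                     int fa_onset, double ldd_shape, double ldd_rate) {
  const int D = n_cols * n_rows;
  if (alpha.size() != D || gamma_max.size() != D)
    stop("alpha/gamma_max must have one entry per deme");
  if (T <= 0) stop("T must be positive");
  if (hg_origin < 1 || hg_origin > D || fa_origin < 1 || fa_origin > D)
    stop("origin deme out of range");
  if (!land[hg_origin - 1] || !land[fa_origin - 1])
    stop("origin deme on water");
  if (ramp && t_inc < 1) stop("t_inc must be >= 1");

  IntegerMatrix N_hg(T + 1, D), N_fa(T + 1, D);
  IntegerMatrix pad_hg(T, D), pad_fa(T, D);
  IntegerMatrix res_hg(T, D), res_fa(T, D);
  IntegerMatrix imm_hg(T, 4 * D), imm_fa(T, 4 * D);
  IntegerMatrix A(T, D);
  IntegerVector colonized_fa(D, -1), cohab_first(D, -1), cohab_last(D, -1);
  int hg_extinct = -1;

  std::vector<int> ldd_g, ldd_src, ldd_dst, ldd_layer, ldd_cnt;

  std::vector<long long> nh(D, 0), nf(D, 0), nh2(D), nf2(D);
  nh[hg_origin - 1] = (long long)std::llround(K_hg);
  N_hg(0, hg_origin - 1) = (int)nh[hg_origin - 1];

  std::vector<long long> arr_h(D), arr_f(D), dep_h(D), dep_f(D);

  for (int g = 1; g <= T; ++g) {
    // FA seeding (before growth)
    if (g == fa_onset) {
      long long seed = (long long)std::llround(K_fa);
      if (nf[fa_origin - 1] < seed) nf[fa_origin - 1] = seed;
      if (colonized_fa[fa_origin - 1] < 0) colonized_fa[fa_origin - 1] = g;
    }
    // 1. logistic growth with Lotka-Volterra competition (simultaneous)
    for (int d = 0; d < D; ++d) {
      nh2[d] = lv_step(nh[d], nf[d], r_hg, K_hg, alpha[d]);
      nf2[d] = lv_step(nf[d], nh[d], r_fa, K_fa, alpha[d]);
    }
    // 2. assimilation admixture HG -> FA where both layers present
    for (int d = 0; d < D; ++d) {
      long long a = 0;
      if (nh2[d] > 0 && nf2[d] > 0 && gamma_max[d] > 0) {
        double gam = gamma_max[d];
        if (ramp) {
          int col = colonized_fa[d];
          double gsc = (col < 0) ? 0.0 : (double)(g - col);
          double f = gsc / t_inc;
          gam *= (f < 0.0 ? 0.0 : (f > 1.0 ? 1.0 : f));
        }
        double ex = gam * (double)nh2[d] * (double)nf2[d] /
                    (double)(nh2[d] + nf2[d]);
        a = (long long)std::floor(ex);
        if (unif_rand() < ex - std::floor(ex)) a += 1;
        if (a > nh2[d]) a = nh2[d];
        nh2[d] -= a;
        nf2[d] += a;
      }
      A(g - 1, d) = (int)a;
      pad_hg(g - 1, d) = (int)nh2[d];
      pad_fa(g - 1, d) = (int)nf2[d];
    }
    // 3. emigration: stepping-stone to the 4 orthogonal neighbours + LDD
    for (int layer = 0; layer < 2; ++layer) {
      std::vector<long long> &n2 = layer == 0 ? nh2 : nf2;
      double m = layer == 0 ? m_hg : m_fa;
      double pl = layer == 0 ? p_ldd_hg : p_ldd_fa;
      IntegerMatrix &imm = layer == 0 ? imm_hg : imm_fa;
      std::vector<long long> &arr = layer == 0 ? arr_h : arr_f;
      std::vector<long long> &dep = layer == 0 ? dep_h : dep_f;
      std::fill(arr.begin(), arr.end(), 0);
      std::fill(dep.begin(), dep.end(), 0);
      std::map<std::pair<int, int>, int> ldd_agg;
      for (int d = 0; d < D; ++d) {
        if (n2[d] <= 0 || m <= 0.0) continue;
        long long E = (long long)R::rbinom((double)n2[d], m);
        if (E == 0) continue;
        long long nl = pl > 0 ? (long long)R::rbinom((double)E, pl) : 0;
        long long ss = E - nl;
        int col = d % n_cols, row = d / n_cols;
        // multinomial split of stepping-stone emigrants over 4 directions
        long long rem = ss;
        for (int k = 0; k < 4; ++k) {
          long long cnt = (k == 3) ? rem
              : (long long)R::rbinom((double)rem, 1.0 / (4 - k));
          rem -= cnt;
          if (cnt == 0) continue;
          int tc = col + DX[k], tr = row + DY[k];
          if (tc < 0 || tc >= n_cols || tr < 0 || tr >= n_rows) continue;
          int dst = tr * n_cols + tc;
          if (!land[dst]) continue;  // blocked migrants stay
          dep[d] += cnt;
          arr[dst] += cnt;
          imm(g - 1, dst * 4 + opp(k)) += (int)cnt;
        }
        // LDD: gamma-distributed distance (deme widths), uniform direction
        for (long long e = 0; e < nl; ++e) {
          int dst = -1;
          for (int tries = 0; tries < 10; ++tries) {
            double dist = R::rgamma(ldd_shape, 1.0 / ldd_rate);
            double th = unif_rand() * 2.0 * M_PI;
            double tx = (col + 0.5) + dist * std::cos(th);
            double ty = (row + 0.5) + dist * std::sin(th);
            int tc = (int)std::floor(tx), tr = (int)std::floor(ty);
            if (tc < 0 || tc >= n_cols || tr < 0 || tr >= n_rows) continue;
            int cand = tr * n_cols + tc;
            if (!land[cand]) continue;
            dst = cand;
            break;
          }
          if (dst < 0 || dst == d) continue;  // exhausted or own cell: stay
          dep[d] += 1;
          arr[dst] += 1;
          ldd_agg[std::make_pair(d, dst)] += 1;
        }
      }
      for (std::map<std::pair<int, int>, int>::iterator it = ldd_agg.begin();
           it != ldd_agg.end(); ++it) {
        ldd_g.push_back(g);
        ldd_src.push_back(it->first.first + 1);
        ldd_dst.push_back(it->first.second + 1);
        ldd_layer.push_back(layer);
        ldd_cnt.push_back(it->second);
      }
      for (int d = 0; d < D; ++d) {
        long long stay = n2[d] - dep[d];
        if (layer == 0) res_hg(g - 1, d) = (int)stay;
        else res_fa(g - 1, d) = (int)stay;
        n2[d] = stay + arr[d];
      }
    }
    // 4. record
    long long tot_hg = 0;
    for (int d = 0; d < D; ++d) {
      nh[d] = nh2[d];
      nf[d] = nf2[d];
      N_hg(g, d) = (int)nh[d];
      N_fa(g, d) = (int)nf[d];
      tot_hg += nh[d];
      if (nf[d] > 0 && colonized_fa[d] < 0) colonized_fa[d] = g;
      if (nh[d] > 0 && nf[d] > 0) {
        if (cohab_first[d] < 0) cohab_first[d] = g;
        cohab_last[d] = g;
      }
    }
    if (tot_hg == 0 && hg_extinct < 0) hg_extinct = g;
  }

  return List::create(
      _["N_hg"] = N_hg, _["N_fa"] = N_fa, _["postadm_hg"] = pad_hg,
      _["postadm_fa"] = pad_fa, _["res_hg"] = res_hg, _["res_fa"] = res_fa,
      _["imm_hg"] = imm_hg, _["imm_fa"] = imm_fa,
      _["ldd"] = DataFrame::create(
          _["g"] = wrap(ldd_g), _["src"] = wrap(ldd_src),
          _["dst"] = wrap(ldd_dst), _["layer"] = wrap(ldd_layer),
          _["count"] = wrap(ldd_cnt)),
      _["A"] = A, _["colonized_fa"] = colonized_fa,
      _["cohab_first"] = cohab_first, _["cohab_last"] = cohab_last,
      _["hg_extinct_gen"] = hg_extinct);
}

// ---------------------------------------------------------------------------
// Backward structured coalescent conditioned on the forward records.
//
// One particle per sampled gene copy per locus. Particles activate at their
// sample's generation (serial sampling) and are traced back one generation
// at a time: (i) pick the migration origin proportional to recorded resident
// / stepping-stone / LDD counts; (ii) for FA-layer particles, become an
// admixture transfer from the HG layer with probability A / N_postadm;
// (iii) pick a uniform parent among the previous generation's copies;
// particles of the same locus choosing the same parent coalesce. FA lineages
// that pre-date the FA seeding coalesce in a panmictic source pool of size
// K_src; everything reaching generation 0 coalesces in a panmictic ancestral
// pool of size K_anc (node times there are negative generations).
// ---------------------------------------------------------------------------

struct Particle {
  int locus;
  int deme;   // 1-based; 0 = FA source pool
  int layer;  // 0 HG, 1 FA
  int node;
};

// [[Rcpp::export]]
List cpp_trace_loci(IntegerMatrix N_hg, IntegerMatrix N_fa,
                    IntegerMatrix pad_fa, IntegerMatrix res_hg,
                    IntegerMatrix res_fa, IntegerMatrix imm_hg,
                    IntegerMatrix imm_fa, DataFrame ldd, IntegerMatrix A,
                    int n_cols, int n_rows, IntegerVector samp_deme,
                    IntegerVector samp_layer, IntegerVector samp_gen,
                    IntegerVector samp_n, int n_loci, int fa_origin,
                    int fa_onset, double K_src, double K_anc) {
  const int D = n_cols * n_rows;
  const int T = N_hg.nrow() - 1;
  const int S = samp_deme.size();
  if (K_src < 1 || K_anc < 1) stop("pool sizes must be >= 1");

  // LDD lookup: key (layer, g, dst) -> rows
  IntegerVector lg = ldd["g"], lsrc = ldd["src"], ldst = ldd["dst"],
                llay = ldd["layer"], lcnt = ldd["count"];
  std::unordered_map<long long, std::vector<int> > ldd_ix;
  for (int i = 0; i < lg.size(); ++i) {
    long long key = (((long long)llay[i] * (T + 1)) + lg[i]) * D +
                    (ldst[i] - 1);
    ldd_ix[key].push_back(i);
  }

  int n_tips = 0, g_max = 0;
  for (int s = 0; s < S; ++s) {
    n_tips += samp_n[s];
    if (samp_gen[s] > g_max) g_max = samp_gen[s];
    if (samp_gen[s] < 0 || samp_gen[s] > T) stop("sample generation outside db");
  }
  if (n_tips < 1) stop("empty sampling scheme");

  std::vector<int> ev_locus, ev_parent, ev_child, nd_locus, nd_id;
  std::vector<double> nd_time;
  std::vector<std::vector<Particle> > act(n_loci);
  std::vector<int> next_node(n_loci, n_tips + 1);

  // activation bookkeeping
  // tips are numbered locus-independently 1..n_tips in sample order
  std::vector<int> tip_sample(n_tips);
  {
    int t = 0;
    for (int s = 0; s < S; ++s)
      for (int i = 0; i < samp_n[s]; ++i) tip_sample[t++] = s;
  }

  for (int g = g_max; g >= 1; --g) {
    // activate samples of this generation
    for (int t = 0; t < n_tips; ++t) {
      int s = tip_sample[t];
      if (samp_gen[s] != g) continue;
      int d = samp_deme[s], lay = samp_layer[s];
      int navail = lay == 0 ? N_hg(g, d - 1) : N_fa(g, d - 1);
      if (navail < 1) stop("sample in empty deme: demographic filter not met");
      for (int l = 0; l < n_loci; ++l) {
        Particle p;
        p.locus = l; p.deme = d; p.layer = lay; p.node = t + 1;
        act[l].push_back(p);
      }
    }
    // step g -> g-1
    for (int l = 0; l < n_loci; ++l) {
      std::vector<Particle> &ps = act[l];
      for (size_t i = 0; i < ps.size(); ++i) {
        Particle &p = ps[i];
        if (p.deme == 0) continue;  // FA source pool: no movement
        int d0 = p.deme - 1;
        IntegerMatrix &N = p.layer == 0 ? N_hg : N_fa;
        IntegerMatrix &res = p.layer == 0 ? res_hg : res_fa;
        IntegerMatrix &imm = p.layer == 0 ? imm_hg : imm_fa;
        long long total = N(g, d0);
        if (total <= 0) stop("lineage in empty deme: bookkeeping corruption");
        double u = unif_rand() * (double)total;
        long long acc = res(g - 1, d0);
        int origin = p.deme;
        if (u >= (double)acc) {
          bool placed = false;
          int col = d0 % n_cols, row = d0 / n_cols;
          for (int k = 0; k < 4 && !placed; ++k) {
            int c = imm(g - 1, d0 * 4 + k);
            if (c == 0) continue;
            acc += c;
            if (u < (double)acc) {
              origin = (row + DY[k]) * n_cols + (col + DX[k]) + 1;
              placed = true;
            }
          }
          if (!placed) {
            long long key = (((long long)p.layer * (T + 1)) + g) * D + d0;
            std::unordered_map<long long, std::vector<int> >::iterator it =
                ldd_ix.find(key);
            if (it != ldd_ix.end()) {
              for (size_t j = 0; j < it->second.size() && !placed; ++j) {
                int r = it->second[j];
                acc += lcnt[r];
                if (u < (double)acc) { origin = lsrc[r]; placed = true; }
              }
            }
            if (!placed) stop("inflow bookkeeping does not sum to N");
          }
        }
        p.deme = origin;
        // admixture origin: FA copies at pre-migration stage may be
        // transfers from the HG layer of the same deme
        if (p.layer == 1) {
          int a = A(g - 1, p.deme - 1);
          if (a > 0) {
            int padm = pad_fa(g - 1, p.deme - 1);
            if (unif_rand() * (double)padm < (double)a) p.layer = 0;
          }
        }
        // FA lineages older than the seeding enter the source pool
        if (p.layer == 1 && g - 1 < fa_onset) {
          if (p.deme != fa_origin)
            stop("FA lineage pre-dates seeding outside the origin deme");
          p.deme = 0;
        }
      }
      // coalescence: same (deme, layer) particles pick parents among the
      // previous generation's copies; equal parents merge
      std::unordered_map<long long, std::vector<int> > groups;
      for (size_t i = 0; i < ps.size(); ++i)
        groups[(long long)(ps[i].deme) * 2 + ps[i].layer].push_back((int)i);
      std::vector<bool> dead(ps.size(), false);
      for (std::unordered_map<long long, std::vector<int> >::iterator it =
               groups.begin(); it != groups.end(); ++it) {
        std::vector<int> &ix = it->second;
        if (ix.size() < 2) continue;
        Particle &p0 = ps[ix[0]];
        double Np;
        if (p0.deme == 0) Np = K_src;
        else Np = p0.layer == 0 ? (double)N_hg(g - 1, p0.deme - 1)
                                : (double)N_fa(g - 1, p0.deme - 1);
        if (Np < 1) stop("zero-size parent pool: bookkeeping corruption");
        std::unordered_map<long long, std::vector<int> > par;
        for (size_t j = 0; j < ix.size(); ++j)
          par[(long long)std::floor(unif_rand() * Np)].push_back(ix[j]);
        for (std::unordered_map<long long, std::vector<int> >::iterator pt =
                 par.begin(); pt != par.end(); ++pt) {
          if (pt->second.size() < 2) continue;
          int w = next_node[l]++;
          nd_locus.push_back(l + 1);
          nd_id.push_back(w);
          nd_time.push_back((double)(g - 1));
          for (size_t j = 0; j < pt->second.size(); ++j) {
            int pi = pt->second[j];
            ev_locus.push_back(l + 1);
            ev_parent.push_back(w);
            ev_child.push_back(ps[pi].node);
            if (j == 0) ps[pi].node = w;
            else dead[pi] = true;
          }
        }
      }
      std::vector<Particle> keep;
      keep.reserve(ps.size());
      for (size_t i = 0; i < ps.size(); ++i)
        if (!dead[i]) keep.push_back(ps[i]);
      ps.swap(keep);
    }
  }

  // generation-0 samples (if any) activate directly into the ancestral pool
  for (int t = 0; t < n_tips; ++t) {
    int s = tip_sample[t];
    if (samp_gen[s] != 0) continue;
    for (int l = 0; l < n_loci; ++l) {
      Particle p;
      p.locus = l; p.deme = 0; p.layer = 0; p.node = t + 1;
      act[l].push_back(p);
    }
  }

  // panmictic ancestral pool of size K_anc until each locus reaches its MRCA
  for (int l = 0; l < n_loci; ++l) {
    std::vector<Particle> &ps = act[l];
    double t = 0;
    long long guard = 0;
    while (ps.size() > 1) {
      if (++guard > 100000000LL) stop("ancestral pool failed to coalesce");
      t += 1.0;
      std::unordered_map<long long, std::vector<int> > par;
      for (size_t i = 0; i < ps.size(); ++i)
        par[(long long)std::floor(unif_rand() * K_anc)].push_back((int)i);
      std::vector<bool> dead(ps.size(), false);
      for (std::unordered_map<long long, std::vector<int> >::iterator pt =
               par.begin(); pt != par.end(); ++pt) {
        if (pt->second.size() < 2) continue;
        int w = next_node[l]++;
        nd_locus.push_back(l + 1);
        nd_id.push_back(w);
        nd_time.push_back(-t);
        for (size_t j = 0; j < pt->second.size(); ++j) {
          int pi = pt->second[j];
          ev_locus.push_back(l + 1);
          ev_parent.push_back(w);
          ev_child.push_back(ps[pi].node);
          if (j == 0) ps[pi].node = w;
          else dead[pi] = true;
        }
      }
      std::vector<Particle> keep;
      keep.reserve(ps.size());
      for (size_t i = 0; i < ps.size(); ++i)
        if (!dead[i]) keep.push_back(ps[i]);
      ps.swap(keep);
    }
  }

  IntegerVector tip_samp(n_tips);
  NumericVector tip_time(n_tips);
  for (int t = 0; t < n_tips; ++t) {
    tip_samp[t] = tip_sample[t] + 1;
    tip_time[t] = (double)samp_gen[tip_sample[t]];
  }
  return List::create(
      _["edges"] = DataFrame::create(_["locus"] = wrap(ev_locus),
                                     _["parent"] = wrap(ev_parent),
                                     _["child"] = wrap(ev_child)),
      _["nodes"] = DataFrame::create(_["locus"] = wrap(nd_locus),
                                     _["id"] = wrap(nd_id),
                                     _["time"] = wrap(nd_time)),
      _["n_tips"] = n_tips, _["tip_sample"] = tip_samp,
      _["tip_time"] = tip_time);
}
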