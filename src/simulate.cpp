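// Batch serial-coalescent engine.
//
// Mirrors the reference R implementation in R/coalsim.R: a serial
// (heterochronous) coalescent with up to two demes, piecewise
// exponential/constant sizes, finite-sites mutation with a
// transition:transversion bias, and the ten-statistic summary panel.
// Each record runs on its own deterministically seeded RNG so results
// are independent of execution partitioning.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <unordered_map>
#include <string>
#include <algorithm>

namespace {

// --- RNG: splitmix64-seeded xoshiro256++ (fixed across platforms) ----

struct Rng {
  uint64_t s[4];
  explicit Rng(uint64_t seed) {
    uint64_t x = seed;
    for (int i = 0; i < 4; ++i) {
      x += 0x9e3779b97f4a7c15ULL;
      uint64_t z = x;
      z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
      z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
      s[i] = z ^ (z >> 31);
    }
  }
  static uint64_t rotl(uint64_t x, int k) { return (x << k) | (x >> (64 - k)); }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  double unif() {  // in (0, 1)
    return ((next() >> 11) + 0.5) * (1.0 / 9007199254740992.0);
  }
  double exp1() { return -std::log(unif()); }
  int unif_int(int n) { return (int)(unif() * n) % n; }
  int poisson(double mean) {
    // exponential inter-arrival summation: exact, O(mean)
    if (mean <= 0) return 0;
    double t = 0; int k = -1;
    while (t <= mean) { t += exp1(); ++k; }
    return k;
  }
};

// --- demographic model ----------------------------------------------

struct Model {
  bool discontinuity, plague;
  double N0, Nanc, Tg, Tdiv, Tp, f, u;
  double r() const { return std::log(N0 / Nanc) / Tg; }
  // main-branch piece at time t: N(t) = C * exp(-r * t)
  void main_piece(double t, double &C, double &rr) const {
    if (t >= Tg) { C = Nanc; rr = 0; return; }
    double scale = (plague && t >= Tp) ? 1.0 / f : 1.0;
    C = scale * N0; rr = r();
  }
};

// waiting: next coalescence time among k lineages from s, capped at end
double piece_wait(double E, int k, double s, double end, double C, double r) {
  if (k < 2) return R_PosInf;
  double rate = 0.5 * k * (k - 1);
  if (r == 0) {
    double x = s + E * C / rate;
    return x > end ? R_PosInf : x;
  }
  double val = std::exp(r * s) + E * C * r / rate;
  if (val <= 0) return R_PosInf;
  double x = std::log(val) / r;
  return x > end ? R_PosInf : x;
}

struct Tree {
  std::vector<int> parent;       // 0-based, -1 = root
  std::vector<double> time;
  int n_tips, n_modern, n_ancient;
  double tmrca, total_length;
};

Tree simulate_tree(const Model &m, int n_anc, int n_mod, double age,
                   Rng &rng) {
  int n_tips = n_anc + n_mod;
  int n_nodes = 2 * n_tips - 1;
  Tree tr;
  tr.parent.assign(n_nodes, -1);
  tr.time.assign(n_nodes, 0.0);
  tr.n_tips = n_tips; tr.n_modern = n_mod; tr.n_ancient = n_anc;
  for (int i = 0; i < n_anc; ++i) tr.time[n_mod + i] = age;

  std::vector<double> bounds;
  bounds.push_back(age);
  if (m.plague) bounds.push_back(m.Tp);
  bounds.push_back(m.Tg);
  if (m.discontinuity) bounds.push_back(m.Tdiv);
  std::sort(bounds.begin(), bounds.end());
  bounds.erase(std::unique(bounds.begin(), bounds.end()), bounds.end());
  size_t b_idx = 0;

  std::vector<int> act1, act2;
  for (int i = 0; i < n_mod; ++i) act1.push_back(i);
  bool entered = (n_anc == 0), merged = !m.discontinuity;
  int next_node = n_tips;
  double t_cur = 0;

  while (true) {
    int k1 = (int)act1.size(), k2 = (int)act2.size();
    if (entered && merged && k1 + k2 <= 1) break;
    double seg_end = (b_idx < bounds.size()) ? bounds[b_idx] : R_PosInf;

    double C, rr;
    m.main_piece(t_cur, C, rr);
    double t1 = piece_wait(rng.exp1(), k1, t_cur, seg_end, C, rr);
    double t2 = (k2 >= 2)
      ? piece_wait(rng.exp1(), k2, t_cur, seg_end, m.Nanc, 0.0)
      : R_PosInf;

    double tmin = std::min(t1, t2);
    if (tmin < seg_end) {
      std::vector<int> &act = (t1 <= t2) ? act1 : act2;
      t_cur = tmin;
      int k = (int)act.size();
      int i = rng.unif_int(k);
      int j = rng.unif_int(k - 1);
      if (j >= i) ++j;
      int a = act[i], b = act[j];
      tr.parent[a] = next_node;
      tr.parent[b] = next_node;
      tr.time[next_node] = t_cur;
      // remove the two, append the parent
      if (i > j) std::swap(i, j);
      act.erase(act.begin() + j);
      act.erase(act.begin() + i);
      act.push_back(next_node);
      ++next_node;
    } else {
      t_cur = seg_end;
      ++b_idx;
      if (t_cur == age && n_anc > 0) {
        std::vector<int> &dest = m.discontinuity ? act2 : act1;
        for (int i = 0; i < n_anc; ++i) dest.push_back(n_mod + i);
        entered = true;
      }
      if (m.discontinuity && t_cur == m.Tdiv) {
        act1.insert(act1.end(), act2.begin(), act2.end());
        act2.clear();
        merged = true;
      }
    }
  }
  tr.tmrca = tr.time[n_nodes - 1];
  double tot = 0;
  for (int i = 0; i < n_nodes; ++i)
    if (tr.parent[i] >= 0) tot += tr.time[tr.parent[i]] - tr.time[i];
  tr.total_length = tot;
  return tr;
}

// --- mutation + summary statistics ----------------------------------

// bases coded 0..3 = A,C,G,T; transitions: A<->G (0<->2), C<->T (1<->3)
inline int mutate_base(int cur, double kappa, Rng &rng) {
  double p_ts = kappa / (kappa + 2.0);
  if (rng.unif() < p_ts) return cur ^ 2;            // transition partner
  // one of the two transversions: flip low bit, optionally the high bit
  int tv1 = cur ^ 1, tv2 = cur ^ 3;
  return rng.unif() < 0.5 ? tv1 : tv2;
}

struct SimStats {
  double K_anc, K_mod, P_anc, P_mod, MPWD_anc, MPWD_mod,
         H_anc, H_mod, FST, AS, tmrca, total_length, n_mut;
};

SimStats simulate_record_cpp(const Model &m, int n_anc, int n_mod,
                             double age, int L, double kappa,
                             const std::vector<int> &ref, uint64_t seed) {
  Rng rng(seed);
  Tree tr = simulate_tree(m, n_anc, n_mod, age, rng);
  int n_nodes = 2 * tr.n_tips - 1;

  // per-branch mutation counts and sites
  std::vector<std::vector<int>> mut_site(n_nodes);
  int total_mut = 0;
  for (int i = 0; i < n_nodes; ++i) {
    if (tr.parent[i] < 0) continue;
    double blen = tr.time[tr.parent[i]] - tr.time[i];
    int nm = rng.poisson(blen * m.u * L);
    mut_site[i].resize(nm);
    for (int j = 0; j < nm; ++j) mut_site[i][j] = rng.unif_int(L);
    total_mut += nm;
  }

  // children lists; iterative pre-order DFS with undo stack carrying
  // the running site-state vector (root state = reference)
  std::vector<std::vector<int>> children(n_nodes);
  int root = -1;
  for (int i = 0; i < n_nodes; ++i) {
    if (tr.parent[i] >= 0) children[tr.parent[i]].push_back(i);
    else root = i;
  }
  std::vector<int> state(ref);
  std::vector<int> touched;  // sites ever mutated (for stat restriction)
  std::vector<std::vector<int>> tip_state(tr.n_tips);

  // frame: (node, child index processed, undo list of (site, old base))
  struct Frame { int node; size_t ci; std::vector<std::pair<int,int>> undo; };
  std::vector<Frame> stack;
  auto enter = [&](int node) {
    Frame f; f.node = node; f.ci = 0;
    for (int s : mut_site[node]) {
      f.undo.push_back({s, state[s]});
      state[s] = mutate_base(state[s], kappa, rng);
      touched.push_back(s);
    }
    if (node < tr.n_tips) tip_state[node] = state;  // full copy (sparse L)
    stack.push_back(std::move(f));
  };
  enter(root);
  while (!stack.empty()) {
    Frame &f = stack.back();
    if (f.ci < children[f.node].size()) {
      int ch = children[f.node][f.ci++];
      enter(ch);
    } else {
      for (auto it = f.undo.rbegin(); it != f.undo.rend(); ++it)
        state[it->first] = it->second;
      stack.pop_back();
    }
  }

  // restrict to touched sites for all statistics
  std::sort(touched.begin(), touched.end());
  touched.erase(std::unique(touched.begin(), touched.end()), touched.end());
  int ns = (int)touched.size();

  // per-tip reduced state strings over touched sites
  std::vector<std::string> red(tr.n_tips, std::string(ns, 0));
  for (int t = 0; t < tr.n_tips; ++t)
    for (int j = 0; j < ns; ++j)
      red[t][j] = (char)tip_state[t][touched[j]];

  // distinct haplotypes with per-population counts
  std::unordered_map<std::string, int> hap_id;
  std::vector<std::string> haps;
  std::vector<int> cnt_mod, cnt_anc;
  for (int t = 0; t < tr.n_tips; ++t) {
    auto ins = hap_id.insert({red[t], (int)haps.size()});
    if (ins.second) {
      haps.push_back(red[t]);
      cnt_mod.push_back(0); cnt_anc.push_back(0);
    }
    int id = ins.first->second;
    if (t < tr.n_modern) cnt_mod[id]++; else cnt_anc[id]++;
  }
  int kdist = (int)haps.size();
  int K_mod = 0, K_anc = 0, K_shared = 0;
  for (int i = 0; i < kdist; ++i) {
    if (cnt_mod[i]) ++K_mod;
    if (cnt_anc[i]) ++K_anc;
    if (cnt_mod[i] && cnt_anc[i]) ++K_shared;
  }

  // pairwise differences between distinct haplotypes
  std::vector<double> dmat((size_t)kdist * kdist, 0.0);
  for (int i = 0; i < kdist; ++i)
    for (int j = i + 1; j < kdist; ++j) {
      int d = 0;
      for (int s = 0; s < ns; ++s) d += (haps[i][s] != haps[j][s]);
      dmat[(size_t)i * kdist + j] = dmat[(size_t)j * kdist + i] = d;
    }

  auto within = [&](const std::vector<int> &cnt, int n) {
    if (n < 2) return 0.0;
    double sum = 0;
    for (int i = 0; i < kdist; ++i) {
      if (!cnt[i]) continue;
      for (int j = i + 1; j < kdist; ++j)
        if (cnt[j]) sum += dmat[(size_t)i * kdist + j] * cnt[i] * cnt[j];
    }
    return sum / (0.5 * n * (n - 1.0));
  };
  auto diversity = [&](const std::vector<int> &cnt, int n) {
    if (n < 2) return 0.0;
    double ss = 0;
    for (int i = 0; i < kdist; ++i) {
      double p = (double)cnt[i] / n;
      ss += p * p;
    }
    return n * (1.0 - ss) / (n - 1.0);
  };

  double mpwd_mod = within(cnt_mod, tr.n_modern);
  double mpwd_anc = within(cnt_anc, tr.n_ancient);
  double hb = 0;
  for (int i = 0; i < kdist; ++i) {
    if (!cnt_anc[i]) continue;
    for (int j = 0; j < kdist; ++j)
      if (cnt_mod[j]) hb += dmat[(size_t)i * kdist + j] * cnt_anc[i] * cnt_mod[j];
  }
  hb /= (double)tr.n_ancient * tr.n_modern;
  double fst = (hb == 0) ? 0.0 : 1.0 - 0.5 * (mpwd_anc + mpwd_mod) / hb;

  // private polymorphic sites (per-site state scan over touched sites)
  int P_mod = 0, P_anc = 0;
  for (int j = 0; j < ns; ++j) {
    bool seen_mod[4] = {false}, seen_anc[4] = {false};
    for (int i = 0; i < kdist; ++i) {
      int st = haps[i][j];
      if (cnt_mod[i]) seen_mod[st] = true;
      if (cnt_anc[i]) seen_anc[st] = true;
    }
    int refb = ref[touched[j]];
    int n_mod_states = 0, n_anc_states = 0;
    for (int b = 0; b < 4; ++b) {
      n_mod_states += seen_mod[b];
      n_anc_states += seen_anc[b];
    }
    if (n_mod_states >= 2) {  // segregating in modern
      bool priv = true;
      for (int b = 0; b < 4; ++b)
        if (b != refb && seen_mod[b] && seen_anc[b]) priv = false;
      if (priv) ++P_mod;
    }
    if (n_anc_states >= 2) {
      bool priv = true;
      for (int b = 0; b < 4; ++b)
        if (b != refb && seen_anc[b] && seen_mod[b]) priv = false;
      if (priv) ++P_anc;
    }
  }

  SimStats st;
  st.K_anc = K_anc; st.K_mod = K_mod;
  st.P_anc = P_anc; st.P_mod = P_mod;
  st.MPWD_anc = mpwd_anc; st.MPWD_mod = mpwd_mod;
  st.H_anc = diversity(cnt_anc, tr.n_ancient);
  st.H_mod = diversity(cnt_mod, tr.n_modern);
  st.FST = fst;
  st.AS = (K_anc > 0) ? (double)K_shared / K_anc : 0.0;
  st.tmrca = tr.tmrca;
  st.total_length = tr.total_length;
  st.n_mut = total_mut;
  return st;
}

Model model_from_row(int topology, const double *p) {
  // parameter column order: N0, N_anc, T_growth, T_div, T_plague,
  // f_plague, u
  Model m;
  m.discontinuity = (topology == 2 || topology == 4);
  m.plague = (topology == 3 || topology == 4);
  m.N0 = p[0]; m.Nanc = p[1]; m.Tg = p[2];
  m.Tdiv = p[3]; m.Tp = p[4]; m.f = p[5]; m.u = p[6];
  return m;
}

}  // namespace

// [[Rcpp::export(name = ".sim_batch_cpp")]]
Rcpp::NumericMatrix sim_batch_cpp(int topology, Rcpp::NumericMatrix params,
                                  int n_ancient, int n_modern,
                                  double ancient_age, int L, double kappa,
                                  Rcpp::IntegerVector ref_codes,
                                  Rcpp::NumericVector seeds) {
  int n = params.nrow();
  if (params.ncol() != 7)
    Rcpp::stop("params must have 7 columns");
  if ((int)ref_codes.size() != L)
    Rcpp::stop("ref_codes must have length L");
  if ((int)seeds.size() != n)
    Rcpp::stop("one seed per record required");
  std::vector<int> ref(ref_codes.begin(), ref_codes.end());
  Rcpp::NumericMatrix out(n, 13);
  Rcpp::CharacterVector cn = Rcpp::CharacterVector::create(
    "K_anc", "K_mod", "P_anc", "P_mod", "MPWD_anc", "MPWD_mod",
    "H_anc", "H_mod", "FST", "AS", "tmrca", "total_length", "n_mut");
  Rcpp::colnames(out) = cn;
  std::vector<double> row(7);
  for (int i = 0; i < n; ++i) {
    if (i % 4096 == 0) Rcpp::checkUserInterrupt();
    for (int j = 0; j < 7; ++j) row[j] = params(i, j);
    Model m = model_from_row(topology, row.data());
    SimStats st = simulate_record_cpp(
      m, n_ancient, n_modern, ancient_age, L, kappa, ref,
      (uint64_t)seeds[i]);
    out(i, 0) = st.K_anc; out(i, 1) = st.K_mod;
    out(i, 2) = st.P_anc; out(i, 3) = st.P_mod;
    out(i, 4) = st.MPWD_anc; out(i, 5) = st.MPWD_mod;
    out(i, 6) = st.H_anc; out(i, 7) = st.H_mod;
    out(i, 8) = st.FST; out(i, 9) = st.AS;
    out(i, 10) = st.tmrca; out(i, 11) = st.total_length;
    out(i, 12) = st.n_mut;
  }
  return out;
}
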