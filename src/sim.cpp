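// Two-population structured-coalescent engine with infinite-sites mutation.
//
// Conventions (ms-style): time in units of 4*N_ref generations; population
// sizes as x = N/N_ref; a pair of lineages in a population of relative size
// x coalesces at rate 2/x, so k lineages coalesce at rate k*(k-1)/x; a
// lineage in population i migrates (backward in time) to j at rate
// 2*M_ij/x_i, where M_ij is the forward number of immigrant individuals per
// generation into i from j (2*N_i*m); theta = 4*N_ref*mu*L; with branch lengths in 4*N_ref generations,
// mutations fall at rate theta per unit branch length (so that E[S] for a
// panmictic constant-size sample is theta * sum_{i<n} 1/i).
//
// Epochs are encoded rows of a matrix (backward time, piecewise):
//   t0, x0_K, g_K, x0_W, g_W, M_KfromW, M_WfromK, merged
// with x_p(t) = x0_p * exp(g_p * (t - t0)) inside the epoch. A merged epoch
// pools all lineages into population 0 of size x0_K.
//
// Summary statistics are accumulated per branch from descendant-tip bitsets
// (n <= 64 haplotypes), so loci with thousands of segregating sites cost no
// more than sparse ones; the haplotype-matrix path draws mutation counts in
// the same RNG order so both paths agree exactly for a given seed.

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <vector>
#include <unordered_set>

using namespace Rcpp;

// ---------------------------------------------------------------------------
// RNG: splitmix64-seeded xoshiro256++ (own stream, independent of R's RNG so
// per-locus streams can be derived by counter).

static inline uint64_t splitmix64(uint64_t &state) {
  uint64_t z = (state += 0x9E3779B97F4A7C15ULL);
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

struct Xoshiro {
  uint64_t s[4];
  explicit Xoshiro(uint64_t seed) {
    uint64_t st = seed;
    for (int i = 0; i < 4; ++i) s[i] = splitmix64(st);
  }
  static inline uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  inline uint64_t next() {
    const uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    const uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  inline double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  // uniform on (0, 1]
  inline double unif_pos() { return 1.0 - unif(); }
  inline double rexp(double rate) { return -std::log(unif_pos()) / rate; }
  inline int runif_int(int n) { return (int)(unif() * n); } // 0..n-1
  int rpois(double lam) {
    if (lam <= 0.0) return 0;
    if (lam < 10.0) { // Knuth product-of-uniforms
      double L = std::exp(-lam), p = 1.0;
      int k = 0;
      do { ++k; p *= unif_pos(); } while (p > L);
      return k - 1;
    }
    // Hormann (1993) PTRS transformed rejection
    const double b = 0.931 + 2.53 * std::sqrt(lam);
    const double a = -0.059 + 0.02483 * b;
    const double inv_alpha = 1.1239 + 1.1328 / (b - 3.4);
    const double v_r = 0.9277 - 3.6224 / (b - 2.0);
    for (;;) {
      double U = unif() - 0.5;
      double V = unif_pos();
      double us = 0.5 - std::fabs(U);
      double kf = std::floor((2.0 * a / us + b) * U + lam + 0.43);
      if (us >= 0.07 && V <= v_r) return (int)kf;
      if (kf < 0.0 || (us < 0.013 && V > us)) continue;
      if (std::log(V) + std::log(inv_alpha) - std::log(a / (us * us) + b) <=
          kf * std::log(lam) - lam - std::lgamma(kf + 1.0)) return (int)kf;
    }
  }
};

// Per-locus seed derivation by counter. Kept exactly representable in a
// double (seed < 2^31, so the result stays below 2^53) so the R wrapper can
// visit the identical per-locus streams; splitmix64 seeding decorrelates the
// linear structure.
static inline double derive_seed(double root, double idx) {
  return root * 1048573.0 + (idx + 1.0) * 7919.0;
}

// ---------------------------------------------------------------------------
// Genealogy simulation.

struct Tree {
  int n;                       // tips
  std::vector<int> parent;     // length 2n-1, root has -1
  std::vector<double> time;    // node times (units of 4*N_ref generations)
  long n_migrations;
};

struct EpochView {
  const double *row; // t0, x0K, gK, x0W, gW, M01, M10, merged
  double t0() const { return row[0]; }
  double x0(int p) const { return p == 0 ? row[1] : row[3]; }
  double g(int p) const { return p == 0 ? row[2] : row[4]; }
  // forward 2NM into pop p from the other pop
  double M(int p) const { return p == 0 ? row[5] : row[6]; }
  bool merged() const { return row[7] != 0.0; }
  double x_at(int p, double t) const {
    double gg = g(p);
    if (gg == 0.0) return x0(p);
    return x0(p) * std::exp(gg * (t - t0()));
  }
};

static Tree simulate_tree(const NumericMatrix &epochs, int nK, int nW,
                          Xoshiro &rng) {
  const int n = nK + nW;
  Tree tree;
  tree.n = n;
  tree.parent.assign(2 * n - 1, -1);
  tree.time.assign(2 * n - 1, 0.0);
  tree.n_migrations = 0;

  // per-population lists of active lineage node ids (O(1) event updates)
  std::vector<int> mem[2];
  mem[0].reserve(n); mem[1].reserve(n);
  for (int i = 0; i < nK; ++i) mem[0].push_back(i);
  for (int i = nK; i < n; ++i) mem[1].push_back(i);
  int k = n, next_node = n;
  const int n_epochs = epochs.nrow();
  std::vector<double> erow(8);

  double t = 0.0;
  long iter = 0;
  const long max_iter = 200000000L;

  for (int e = 0; e < n_epochs && k > 1; ++e) {
    for (int c = 0; c < 8; ++c) erow[c] = epochs(e, c);
    EpochView ep{erow.data()};
    double t_end = (e + 1 < n_epochs) ? epochs(e + 1, 0) : R_PosInf;
    if (t < ep.t0()) t = ep.t0();
    if (ep.merged() && !mem[1].empty()) {
      mem[0].insert(mem[0].end(), mem[1].begin(), mem[1].end());
      mem[1].clear();
    }
    const bool constant = ep.g(0) == 0.0 && ep.g(1) == 0.0;
    while (k > 1 && t < t_end) {
      if (++iter > max_iter)
        stop("coalescent iteration cap exceeded (pathological parameters?)");
      const int k0 = (int)mem[0].size(), k1 = (int)mem[1].size();
      const int kp[2] = {k0, k1};
      // rate bound from the minimal population size over the remaining epoch
      // (equals the actual rate in constant-size epochs, so nothing is thinned)
      double lam_max = 0.0;
      for (int p = 0; p < 2; ++p) {
        double gg = ep.g(p);
        double xmin = (gg < 0.0 && R_finite(t_end)) ? ep.x_at(p, t_end)
                                                    : ep.x_at(p, t);
        double r = 0.0;
        if (kp[p] >= 2) r += (double)kp[p] * (kp[p] - 1);
        if (!ep.merged() && kp[p] >= 1) r += 2.0 * ep.M(p) * kp[p];
        lam_max += r / xmin;
      }
      if (lam_max <= 0.0) { t = t_end; break; }
      double t_new = t + rng.rexp(lam_max);
      if (t_new >= t_end) { t = t_end; break; }
      t = t_new;
      // actual rates at the proposed time
      double coal[2], mig[2], lam;
      if (constant) {
        lam = lam_max;
        for (int p = 0; p < 2; ++p) {
          double x = ep.x0(p);
          coal[p] = kp[p] >= 2 ? (double)kp[p] * (kp[p] - 1) / x : 0.0;
          mig[p] = (!ep.merged() && kp[p] >= 1) ? 2.0 * ep.M(p) * kp[p] / x : 0.0;
        }
      } else {
        lam = 0.0;
        for (int p = 0; p < 2; ++p) {
          double x = ep.x_at(p, t_new);
          coal[p] = kp[p] >= 2 ? (double)kp[p] * (kp[p] - 1) / x : 0.0;
          mig[p] = (!ep.merged() && kp[p] >= 1) ? 2.0 * ep.M(p) * kp[p] / x : 0.0;
          lam += coal[p] + mig[p];
        }
      }
      double u = rng.unif() * lam_max;
      if (u >= lam) continue; // thinned (time-varying rates)
      // choose event category by scanning the accumulated rates
      int p;
      bool is_coal;
      if (u < coal[0]) { p = 0; is_coal = true; }
      else if (u < coal[0] + coal[1]) { p = 1; is_coal = true; }
      else if (u < coal[0] + coal[1] + mig[0]) { p = 0; is_coal = false; }
      else { p = 1; is_coal = false; }
      if (is_coal) {
        int i1 = rng.runif_int(kp[p]);
        int i2 = rng.runif_int(kp[p] - 1);
        if (i2 >= i1) ++i2;
        int a = mem[p][i1], b = mem[p][i2];
        int node = next_node++;
        tree.time[node] = t;
        tree.parent[a] = node;
        tree.parent[b] = node;
        mem[p][i1] = node;
        if (i2 == (int)mem[p].size() - 1) mem[p].pop_back();
        else { mem[p][i2] = mem[p].back(); mem[p].pop_back(); }
        --k;
      } else {
        int i1 = rng.runif_int(kp[p]);
        int a = mem[p][i1];
        if (i1 == (int)mem[p].size() - 1) mem[p].pop_back();
        else { mem[p][i1] = mem[p].back(); mem[p].pop_back(); }
        mem[1 - p].push_back(a);
        tree.n_migrations++;
      }
    }
  }
  if (k > 1) stop("genealogy did not fully coalesce (timeline lacks a merged terminal epoch)");
  return tree;
}

// descendant-tip bitsets per node (n <= 64)
static void node_bitsets(const Tree &tree, std::vector<uint64_t> &bits) {
  const int m = 2 * tree.n - 1;
  bits.assign(m, 0ULL);
  for (int i = 0; i < tree.n; ++i) bits[i] = 1ULL << i;
  for (int v = 0; v < m - 1; ++v) bits[tree.parent[v]] |= bits[v];
}

// ---------------------------------------------------------------------------
// Summary statistics from per-branch mutation multiplicities.

static double tajima_d(double S, double pi_sum, int n) {
  if (n < 4 || S < 3.0) return NA_REAL;
  double a1 = 0.0, a2 = 0.0;
  for (int i = 1; i <= n - 1; ++i) { a1 += 1.0 / i; a2 += 1.0 / ((double)i * i); }
  double b1 = (n + 1.0) / (3.0 * (n - 1.0));
  double b2 = 2.0 * ((double)n * n + n + 3.0) / (9.0 * n * (n - 1.0));
  double c1 = b1 - 1.0 / a1;
  double c2 = b2 - (n + 2.0) / (a1 * n) + a2 / (a1 * a1);
  double e1 = c1 / a1;
  double e2 = c2 / (a1 * a1 + a2);
  double denom = std::sqrt(e1 * S + e2 * S * (S - 1.0));
  if (denom <= 0.0) return NA_REAL;
  return (pi_sum - S / a1) / denom;
}

struct BranchSite {
  uint64_t bits;
  double m;   // number of mutations on this branch
  double p;   // pooled derived frequency
};

// Stats vector layout (keep in sync with R side):
// S, pi_K, pi_W, D_K, D_W, D_pool, fst_wc, dxy, d_f, r2_mean
static void accumulate_stats(const Tree &tree, int nK, int nW, double theta,
                             double L, Xoshiro &rng, double *out,
                             std::vector<double> *mut_out,
                             bool with_r2 = true) {
  const int n = nK + nW;
  const int m_nodes = 2 * n - 1;
  std::vector<uint64_t> bits;
  node_bitsets(tree, bits);

  const uint64_t maskK = (nK == 64) ? ~0ULL : ((1ULL << nK) - 1ULL);
  const uint64_t maskAll = (n == 64) ? ~0ULL : ((1ULL << n) - 1ULL);
  const uint64_t maskW = maskAll & ~maskK;
  const uint64_t even = 0x5555555555555555ULL;
  const bool diploid_ok = (nK % 2 == 0) && (nW % 2 == 0) && nK >= 2 && nW >= 2;

  double S = 0.0, SK = 0.0, SW = 0.0;
  double piK_sum = 0.0, piW_sum = 0.0, piP_sum = 0.0, dxy_sum = 0.0, df = 0.0;
  double A = 0.0, B = 0.0, C = 0.0; // WC variance components (ratio of sums)

  std::vector<BranchSite> seg;
  seg.reserve(m_nodes);
  if (mut_out) mut_out->assign(m_nodes - 1, 0.0);

  for (int v = 0; v < m_nodes - 1; ++v) {
    double len = tree.time[tree.parent[v]] - tree.time[v];
    double mb = (double)rng.rpois(len * theta);
    if (mut_out) (*mut_out)[v] = mb;
    if (mb <= 0.0) continue;
    uint64_t d = bits[v];
    int dk = __builtin_popcountll(d & maskK);
    int dw = __builtin_popcountll(d & maskW);
    int dt = dk + dw;
    S += mb;
    if (dk > 0 && dk < nK) SK += mb;
    if (dw > 0 && dw < nW) SW += mb;
    if (nK >= 2) piK_sum += mb * 2.0 * dk * (nK - dk) / ((double)nK * (nK - 1));
    if (nW >= 2) piW_sum += mb * 2.0 * dw * (nW - dw) / ((double)nW * (nW - 1));
    piP_sum += mb * 2.0 * dt * (n - dt) / ((double)n * (n - 1));
    if (nK > 0 && nW > 0)
      dxy_sum += mb * ((double)dk * (nW - dw) + (double)dw * (nK - dk)) /
                 ((double)nK * nW);
    if (nK > 0 && nW > 0 &&
        ((dk == nK && dw == 0) || (dk == 0 && dw == nW))) df += mb;
    if (diploid_ok) {
      // Weir & Cockerham (1984), r = 2 populations of diploids formed by
      // pairing consecutive haplotypes
      double n1 = nK / 2.0, n2 = nW / 2.0;
      double p1 = (double)dk / nK, p2 = (double)dw / nW;
      double h1 = __builtin_popcountll((d ^ (d >> 1)) & even & maskK) / n1;
      double h2 = __builtin_popcountll((d ^ (d >> 1)) & even & maskW) / n2;
      double nbar = (n1 + n2) / 2.0;
      double nsum = n1 + n2;
      double nc = nsum - (n1 * n1 + n2 * n2) / nsum;
      double pbar = (n1 * p1 + n2 * p2) / nsum;
      double s2 = (n1 * (p1 - pbar) * (p1 - pbar) +
                   n2 * (p2 - pbar) * (p2 - pbar)) / nbar;
      double hbar = (n1 * h1 + n2 * h2) / nsum;
      double a = (nbar / nc) *
                 (s2 - (pbar * (1.0 - pbar) - s2 / 2.0 - hbar / 4.0) / (nbar - 1.0));
      double b = (nbar / (nbar - 1.0)) *
                 (pbar * (1.0 - pbar) - s2 / 2.0 - hbar * (2.0 * nbar - 1.0) / (4.0 * nbar));
      double c = hbar / 2.0;
      A += mb * a; B += mb * b; C += mb * c;
    }
    if (with_r2) {
      BranchSite bs;
      bs.bits = d;
      bs.m = mb;
      bs.p = (double)dt / n;
      seg.push_back(bs);
    }
  }

  // mean r^2 over all pairs of segregating sites (haplotype-based)
  double r2_mean = NA_REAL;
  if (with_r2 && S >= 2.0) {
    double tot = 0.0;
    for (size_t i = 0; i < seg.size(); ++i)
      tot += seg[i].m * (seg[i].m - 1.0) / 2.0; // same pattern: r^2 = 1
    for (size_t i = 0; i < seg.size(); ++i) {
      for (size_t j = i + 1; j < seg.size(); ++j) {
        double pA = seg[i].p, pB = seg[j].p;
        double pAB = __builtin_popcountll(seg[i].bits & seg[j].bits) / (double)n;
        double D = pAB - pA * pB;
        double den = pA * (1.0 - pA) * pB * (1.0 - pB);
        if (den > 0.0) tot += seg[i].m * seg[j].m * (D * D / den);
      }
    }
    r2_mean = tot / (S * (S - 1.0) / 2.0);
  }

  out[0] = S;
  out[1] = nK >= 2 ? piK_sum / L : NA_REAL;
  out[2] = nW >= 2 ? piW_sum / L : NA_REAL;
  out[3] = tajima_d(SK, piK_sum, nK);
  out[4] = tajima_d(SW, piW_sum, nW);
  out[5] = tajima_d(S, piP_sum, n);
  double den = A + B + C;
  out[6] = (diploid_ok && S > 0.0 && den != 0.0) ? A / den : NA_REAL;
  out[7] = (nK > 0 && nW > 0) ? dxy_sum / L : NA_REAL;
  out[8] = (nK > 0 && nW > 0) ? df : NA_REAL;
  out[9] = r2_mean;
}

// ---------------------------------------------------------------------------
// Exported interface.

//' @noRd
// [[Rcpp::export(name = ".sim_tree_cpp")]]
List sim_tree_cpp(NumericMatrix epochs, int n_K, int n_W, double seed) {
  if (n_K + n_W < 2) stop("need at least two haplotypes");
  if (n_K + n_W > 64) stop("fast simulation path supports at most 64 haplotypes");
  Xoshiro rng((uint64_t)seed);
  Tree tree = simulate_tree(epochs, n_K, n_W, rng);
  return List::create(_["parent"] = IntegerVector(tree.parent.begin(), tree.parent.end()),
                      _["time"] = NumericVector(tree.time.begin(), tree.time.end()),
                      _["n_tips"] = tree.n,
                      _["n_migrations"] = (double)tree.n_migrations);
}

//' @noRd
// [[Rcpp::export(name = ".sim_locus_stats_cpp")]]
NumericVector sim_locus_stats_cpp(NumericMatrix epochs, int n_K, int n_W,
                                  double theta, double L, double seed) {
  if (n_K + n_W > 64) stop("fast simulation path supports at most 64 haplotypes");
  Xoshiro rng((uint64_t)seed);
  Tree tree = simulate_tree(epochs, n_K, n_W, rng);
  NumericVector out(10);
  accumulate_stats(tree, n_K, n_W, theta, L, rng, REAL(out), nullptr);
  out.attr("names") = CharacterVector::create("S", "pi_K", "pi_W", "D_K", "D_W",
                                              "D_pool", "fst", "dxy", "df", "r2");
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".sim_dataset_stats_cpp")]]
NumericMatrix sim_dataset_stats_cpp(NumericMatrix epochs, int n_K, int n_W,
                                    double theta, double L, int n_loci,
                                    double seed, bool compute_r2 = true) {
  if (n_K + n_W > 64) stop("fast simulation path supports at most 64 haplotypes");
  NumericMatrix out(10, n_loci);
  for (int l = 0; l < n_loci; ++l) {
    Xoshiro rng((uint64_t)derive_seed(seed, (double)l));
    Tree tree = simulate_tree(epochs, n_K, n_W, rng);
    accumulate_stats(tree, n_K, n_W, theta, L, rng, &out(0, l), nullptr,
                     compute_r2);
  }
  out.attr("dimnames") = List::create(
      CharacterVector::create("S", "pi_K", "pi_W", "D_K", "D_W", "D_pool",
                              "fst", "dxy", "df", "r2"),
      R_NilValue);
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".sim_locus_haplotypes_cpp")]]
List sim_locus_haplotypes_cpp(NumericMatrix epochs, int n_K, int n_W,
                              double theta, double L, double seed) {
  if (n_K + n_W > 64) stop("fast simulation path supports at most 64 haplotypes");
  const int n = n_K + n_W;
  Xoshiro rng((uint64_t)seed);
  Tree tree = simulate_tree(epochs, n_K, n_W, rng);
  // draw per-branch mutation counts in the same order as the stats path
  NumericVector stats(10);
  std::vector<double> mut;
  accumulate_stats(tree, n_K, n_W, theta, L, rng, REAL(stats), &mut);
  stats.attr("names") = CharacterVector::create("S", "pi_K", "pi_W", "D_K", "D_W",
                                                "D_pool", "fst", "dxy", "df", "r2");
  std::vector<uint64_t> bits;
  node_bitsets(tree, bits);
  long total = 0;
  for (double m : mut) total += (long)m;
  if ((double)total > L)
    stop("more mutations than sites: locus length too short for theta (infinite-sites approximation breaks down)");
  // unique integer positions on [0, L); collisions redrawn
  std::unordered_set<long> used;
  used.reserve((size_t)(total * 1.4) + 8);
  std::vector<long> pos(total);
  std::vector<int> branch_of(total);
  long idx = 0;
  for (size_t v = 0; v < mut.size(); ++v) {
    for (long j = 0; j < (long)mut[v]; ++j) {
      long p;
      do { p = (long)(rng.unif() * L); } while (used.count(p));
      used.insert(p);
      pos[idx] = p;
      branch_of[idx] = (int)v;
      ++idx;
    }
  }
  // sort columns by position
  std::vector<long> ord(total);
  for (long i = 0; i < total; ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(),
            [&](long a, long b) { return pos[a] < pos[b]; });
  IntegerMatrix mat(n, (int)total);
  IntegerVector positions((int)total);
  for (long c = 0; c < total; ++c) {
    long i = ord[c];
    positions[(int)c] = (int)pos[i];
    uint64_t d = bits[branch_of[i]];
    for (int r = 0; r < n; ++r) mat(r, (int)c) = (int)((d >> r) & 1ULL);
  }
  return List::create(_["haplotypes"] = mat, _["positions"] = positions,
                      _["stats"] = stats,
                      _["tmrca"] = tree.time[2 * n - 2],
                      _["n_migrations"] = (double)tree.n_migrations);
}
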