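// Compiled core for Boolean threshold network dynamics and evolution.
//
// States are length-N vectors over {-1,+1}, encoded as N-bit masks
// (bit i set <=> s_i == +1). Network rows are likewise bit-packed:
// pos[i] holds the +1 entries of row i, nz[i] the non-zero support.
// The synchronous update s'_i = sgn(sum_j w_ij s_j), sgn(0) = +1,
// reduces to a popcount: sum_j w_ij s_j = 2*matches - nnz_i where
// matches = |{j in support : w_ij == s_j}|, so s'_i = +1 iff
// 2*matches >= nnz_i. All arithmetic is exact integer work.
//
// Compiled batch paths require N <= 20 (mark table of size 2^N);
// the regime of interest is N = 10.

#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <vector>
#include <algorithm>
#include <cstdint>

using namespace Rcpp;

static inline int popcnt(uint32_t x) { return __builtin_popcount(x); }

static inline uint32_t encode_state(const int* s, int N) {
  uint32_t c = 0;
  for (int i = 0; i < N; ++i) if (s[i] > 0) c |= (1u << i);
  return c;
}

static inline void decode_state(uint32_t c, int N, int* out) {
  for (int i = 0; i < N; ++i) out[i] = ((c >> i) & 1u) ? 1 : -1;
}

// ---------------------------------------------------------------------------
// General single-network attractor detection (hash map; N <= 31).
// Transient = index of first recurrent state; cycle = states between the
// two visits of that state. max_steps caps the number of states examined.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List attractor_cpp(IntegerMatrix W, IntegerVector s0, double max_steps) {
  const int N = W.nrow();
  if (W.ncol() != N)
    stop("network matrix must be square");
  if (s0.size() != N)
    stop("state length (%d) does not match network size (%d)",
         (int)s0.size(), N);
  if (N > 31) stop("attractor detection supports at most 31 genes");

  std::vector<int> s(s0.begin(), s0.end()), nxt(N);
  std::unordered_map<uint32_t, int> seen;
  std::vector<uint32_t> traj;

  int t = 0;
  for (;;) {
    const uint32_t code = encode_state(s.data(), N);
    auto it = seen.find(code);
    if (it != seen.end()) {
      const int first = it->second, l = t - first;
      IntegerMatrix cyc(l, N);
      std::vector<int> buf(N);
      for (int k = 0; k < l; ++k) {
        decode_state(traj[first + k], N, buf.data());
        for (int i = 0; i < N; ++i) cyc(k, i) = buf[i];
      }
      return List::create(_["transient"] = first, _["length"] = l,
                          _["cycle"] = cyc);
    }
    if ((double)t >= max_steps)
      stop("no attractor detected within max_steps; use max_steps >= 2^N + 1");
    seen.emplace(code, t);
    traj.push_back(code);
    for (int i = 0; i < N; ++i) {
      long acc = 0;
      for (int j = 0; j < N; ++j) acc += (long)W(i, j) * s[j];
      nxt[i] = (acc >= 0) ? 1 : -1;
    }
    s = nxt;
    ++t;
  }
}

// ---------------------------------------------------------------------------
// Bit-packed development to attractor. mark is a reusable table of size
// 2^N initialised to -1; it is restored before returning. traj receives
// the visited state codes (transient then cycle).
// ---------------------------------------------------------------------------

static bool dev_bits(const uint32_t* pos, const uint32_t* nz, const int* nnz,
                     int N, uint32_t s, double max_steps,
                     std::vector<int>& mark, std::vector<uint32_t>& traj,
                     int& transient, int& len) {
  traj.clear();
  int t = 0;
  for (;;) {
    if (mark[s] >= 0) {
      transient = mark[s];
      len = t - transient;
      break;
    }
    if ((double)t >= max_steps) {
      for (uint32_t c : traj) mark[c] = -1;
      return false;
    }
    mark[s] = t;
    traj.push_back(s);
    uint32_t ns = 0;
    for (int i = 0; i < N; ++i) {
      const int m = popcnt((~(pos[i] ^ s)) & nz[i]);
      if (2 * m >= nnz[i]) ns |= (1u << i);
    }
    s = ns;
    ++t;
  }
  for (uint32_t c : traj) mark[c] = -1;
  return true;
}

// Pack network k of a column-major N x N x n integer array.
static void pack_net(const int* w, int N, uint32_t* pos, uint32_t* nz,
                     int* nnz) {
  for (int i = 0; i < N; ++i) { pos[i] = 0; nz[i] = 0; nnz[i] = 0; }
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      const int v = w[j * N + i];
      if (v != 0) {
        nz[i] |= (1u << j);
        ++nnz[i];
        if (v > 0) pos[i] |= (1u << j);
      }
    }
}

static void unpack_net(const uint32_t* pos, const uint32_t* nz, int N,
                       int* w) {
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) {
      int v = 0;
      if ((nz[i] >> j) & 1u) v = ((pos[i] >> j) & 1u) ? 1 : -1;
      w[j * N + i] = v;
    }
}

static void check_batch_N(int N) {
  if (N < 1 || N > 20)
    stop("compiled batch dynamics support 1 <= N <= 20");
}

// ---------------------------------------------------------------------------
// Batch development of n networks. states is N x n (or N x 1 when shared).
// Returns attractor length, transient, and the fixed-point state code
// (NA when the attractor is a cycle).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List batch_develop_cpp(IntegerVector nets, int N, int n,
                       IntegerMatrix states, bool shared_state,
                       double max_steps) {
  check_batch_N(N);
  if (nets.size() != (R_xlen_t)N * N * n)
    stop("network array size does not match N and n");
  if (states.nrow() != N)
    stop("state length does not match network size");
  if (!shared_state && states.ncol() != n)
    stop("need one state per network");

  IntegerVector lens(n), trans(n);
  IntegerMatrix fp(N, n);
  std::vector<int> mark(1u << N, -1);
  std::vector<uint32_t> traj;
  std::vector<uint32_t> pos(N), nz(N);
  std::vector<int> nnz(N), sbuf(N);

  uint32_t scode0 = 0;
  if (shared_state) {
    for (int i = 0; i < N; ++i) sbuf[i] = states(i, 0);
    scode0 = encode_state(sbuf.data(), N);
  }
  for (int k = 0; k < n; ++k) {
    pack_net(&nets[(R_xlen_t)k * N * N], N, pos.data(), nz.data(), nnz.data());
    uint32_t sc = scode0;
    if (!shared_state) {
      for (int i = 0; i < N; ++i) sbuf[i] = states(i, k);
      sc = encode_state(sbuf.data(), N);
    }
    int tr, l;
    if (!dev_bits(pos.data(), nz.data(), nnz.data(), N, sc, max_steps, mark,
                  traj, tr, l))
      stop("no attractor detected within max_steps");
    lens[k] = l;
    trans[k] = tr;
    if (l == 1) {
      decode_state(traj[tr], N, sbuf.data());
      for (int i = 0; i < N; ++i) fp(i, k) = sbuf[i];
    } else {
      for (int i = 0; i < N; ++i) fp(i, k) = NA_INTEGER;
    }
  }
  return List::create(_["length"] = lens, _["transient"] = trans,
                      _["fixed_point"] = fp);
}

// ---------------------------------------------------------------------------
// Single-mutant scan. Flips each non-zero entry in turn and develops from
// s0. The wild type must reach a fixed point (checked here). Per-element
// matrices hold NA at structural zeros (sparse networks).
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List mutant_scan_cpp(IntegerMatrix W, IntegerVector s0, double max_steps) {
  const int N = W.nrow();
  check_batch_N(N);
  if (W.ncol() != N) stop("network matrix must be square");
  if (s0.size() != N) stop("state length does not match network size");

  std::vector<uint32_t> pos(N), nz(N);
  std::vector<int> nnz(N), sbuf(s0.begin(), s0.end());
  std::vector<int> wcol((R_xlen_t)N * N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) wcol[j * N + i] = W(i, j);
  pack_net(wcol.data(), N, pos.data(), nz.data(), nnz.data());

  std::vector<int> mark(1u << N, -1);
  std::vector<uint32_t> traj;
  const uint32_t sc = encode_state(sbuf.data(), N);

  int tr, l;
  if (!dev_bits(pos.data(), nz.data(), nnz.data(), N, sc, max_steps, mark,
                traj, tr, l))
    stop("no attractor detected within max_steps");
  if (l != 1)
    stop("wild-type (W, S0) does not reach a fixed point; the mutant scan is defined for stable originals only");
  const uint32_t wt_fp = traj[tr];

  IntegerMatrix fixed(N, N), same(N, N);
  int n_fixed = 0, n_same = 0, n_total = 0;
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      if (!((nz[i] >> j) & 1u)) {
        fixed(i, j) = NA_INTEGER;
        same(i, j) = NA_INTEGER;
        continue;
      }
      ++n_total;
      pos[i] ^= (1u << j);  // sign flip of w_ij
      int mtr, ml;
      if (!dev_bits(pos.data(), nz.data(), nnz.data(), N, sc, max_steps, mark,
                    traj, mtr, ml))
        stop("no attractor detected within max_steps");
      const bool fx = (ml == 1);
      const bool sm = fx && (traj[mtr] == wt_fp);
      fixed(i, j) = fx ? 1 : 0;
      same(i, j) = sm ? 1 : 0;
      n_fixed += fx;
      n_same += sm;
      pos[i] ^= (1u << j);
    }
  return List::create(_["n_total"] = n_total, _["n_fixed"] = n_fixed,
                      _["n_same"] = n_same, _["fixed"] = fixed,
                      _["same"] = same);
}

// ---------------------------------------------------------------------------
// Wright-Fisher evolution engine (RNIC setup: one shared founding state,
// re-used every generation). Per generation:
//   develop all -> record metrics -> select (fitness-proportional, with
//   replacement) -> recombine (optional, row segregation) -> mutate.
// Metrics p, q, stability and mean fitness are recorded every generation;
// r, viability/robustness scans and the positive-interaction-strength
// matrix o_ij only at scan_gens (they dominate the cost).
// Uses R's RNG (seed via set.seed before calling).
// ---------------------------------------------------------------------------

struct Model {
  int id;        // 1..4
  double sigma;  // may be +Inf
  int l_opt;
  bool has_target;
  uint32_t target;
};

static inline double fitness_bits(const Model& M, int N, int len,
                                  const std::vector<uint32_t>& traj,
                                  int transient) {
  switch (M.id) {
  case 1:
    if (len != 1) return 0.0;
    if (!M.has_target) return 1.0;
    return std::exp(-(popcnt(traj[transient] ^ M.target) / (double)N) /
                    M.sigma);
  case 2:
    return (len == M.l_opt) ? 1.0 : 0.0;
  case 3: {
    int dmin = N + 1;
    for (int k = 0; k < len; ++k) {
      const int d = popcnt(traj[transient + k] ^ M.target);
      if (d < dmin) dmin = d;
    }
    return std::exp(-(dmin / (double)N) / M.sigma);
  }
  default:
    return 1.0;
  }
}

// [[Rcpp::export]]
List evolve_engine_cpp(IntegerVector nets0, int N, int n, IntegerVector s0,
                       int model_id, double sigma, int l_opt,
                       IntegerVector target, double mu, bool recomb,
                       bool sparse, int generations, IntegerVector scan_gens,
                       double max_steps) {
  check_batch_N(N);
  if (nets0.size() != (R_xlen_t)N * N * n)
    stop("network array size does not match N and n");
  if (s0.size() != N) stop("state length does not match network size");
  if (recomb && (n % 2))
    stop("recombination requires an even population size");

  Model M;
  M.id = model_id;
  M.sigma = sigma;
  M.l_opt = l_opt;
  M.has_target = target.size() > 0;
  if (M.has_target) {
    std::vector<int> tb(target.begin(), target.end());
    M.target = encode_state(tb.data(), N);
  } else {
    M.target = 0;
    if (model_id == 1 && !std::isinf(sigma))
      stop("selection model 1 with finite sigma requires a target state");
    if (model_id == 3) stop("selection model 3 requires a target state");
  }

  // bit-packed population (double-buffered)
  std::vector<uint32_t> pos((size_t)n * N), nz((size_t)n * N);
  std::vector<uint32_t> pos2((size_t)n * N), nz2((size_t)n * N);
  std::vector<int> nnz((size_t)n * N), nnz2((size_t)n * N);
  for (int k = 0; k < n; ++k)
    pack_net(&nets0[(R_xlen_t)k * N * N], N, &pos[(size_t)k * N],
             &nz[(size_t)k * N], &nnz[(size_t)k * N]);

  std::vector<int> sbuf(s0.begin(), s0.end());
  const uint32_t sc0 = encode_state(sbuf.data(), N);

  std::vector<int> mark(1u << N, -1);
  std::vector<uint32_t> traj;
  std::vector<double> fit(n), cum(n);
  std::vector<int> lens(n), trans_(n);
  std::vector<uint32_t> fpc(n);

  const int S = scan_gens.size();
  std::unordered_set<int> scan_set(scan_gens.begin(), scan_gens.end());
  NumericMatrix pergen(generations + 1, 5);
  colnames(pergen) = CharacterVector::create("generation", "mean_p", "mean_q",
                                             "stability", "mean_fitness");
  NumericMatrix scans(S, 7);
  colnames(scans) = CharacterVector::create(
      "generation", "mean_r", "viability", "robustness", "n_stable",
      "n_robustness_defined", "n_scanned_mutants");
  NumericMatrix oij((R_xlen_t)N * N, S);
  int scan_row = 0;
  int rescues = 0;

  std::vector<int> idx(n), rowidx(N);
  std::vector<int> nzlist;  // sparse mutation support (rebuilt per gen)

  for (int gen = 0; gen <= generations; ++gen) {
    // develop + fitness + cheap metrics
    long pdiag_pos = 0, pdiag_nz = 0, qoff_pos = 0, qoff_nz = 0;
    int n_stable = 0;
    double fsum = 0.0;
    for (int k = 0; k < n; ++k) {
      const uint32_t* kp = &pos[(size_t)k * N];
      const uint32_t* kz = &nz[(size_t)k * N];
      int tr, l;
      if (!dev_bits(kp, kz, &nnz[(size_t)k * N], N, sc0, max_steps, mark,
                    traj, tr, l))
        stop("no attractor detected within max_steps");
      lens[k] = l;
      trans_[k] = tr;
      fpc[k] = (l == 1) ? traj[tr] : 0;
      if (l == 1) ++n_stable;
      fit[k] = fitness_bits(M, N, l, traj, tr);
      fsum += fit[k];
      for (int i = 0; i < N; ++i) {
        const uint32_t diagbit = (kz[i] >> i) & 1u;
        pdiag_nz += diagbit;
        pdiag_pos += diagbit & (kp[i] >> i);
        const uint32_t off = kz[i] & ~(1u << i);
        qoff_nz += popcnt(off);
        qoff_pos += popcnt(off & kp[i]);
      }
    }
    pergen(gen, 0) = gen;
    pergen(gen, 1) = pdiag_nz ? pdiag_pos / (double)pdiag_nz : NA_REAL;
    pergen(gen, 2) = qoff_nz ? qoff_pos / (double)qoff_nz : NA_REAL;
    pergen(gen, 3) = n_stable / (double)n;
    pergen(gen, 4) = fsum / n;

    if (scan_set.count(gen)) {
      // mean r: fraction of strictly positive upper-triangle entries of W W^T
      double rsum = 0.0;
      const double npairs = N * (N - 1) / 2.0;
      for (int k = 0; k < n; ++k) {
        const uint32_t* kp = &pos[(size_t)k * N];
        const uint32_t* kz = &nz[(size_t)k * N];
        int rpos = 0;
        for (int i = 0; i < N; ++i)
          for (int j = i + 1; j < N; ++j) {
            const uint32_t both = kz[i] & kz[j];
            const int m = popcnt((~(kp[i] ^ kp[j])) & both);
            if (2 * m - popcnt(both) > 0) ++rpos;
          }
        rsum += rpos / npairs;
      }
      // viability / robustness over stable organisms
      double vsum = 0.0, rbsum = 0.0;
      int nsc = 0, nrb = 0;
      long nmut = 0;
      std::vector<uint32_t> mpos(N);
      for (int k = 0; k < n; ++k) {
        if (lens[k] != 1) continue;
        ++nsc;
        const uint32_t wt = fpc[k];
        std::copy(&pos[(size_t)k * N], &pos[(size_t)k * N] + N, mpos.begin());
        const uint32_t* kz = &nz[(size_t)k * N];
        int nfix = 0, nsame = 0, ntot = 0;
        for (int i = 0; i < N; ++i) {
          uint32_t supp = kz[i];
          while (supp) {
            const int j = __builtin_ctz(supp);
            supp &= supp - 1;
            ++ntot;
            mpos[i] ^= (1u << j);
            int mtr, ml;
            if (!dev_bits(mpos.data(), kz, &nnz[(size_t)k * N], N, sc0,
                          max_steps, mark, traj, mtr, ml))
              stop("no attractor detected within max_steps");
            if (ml == 1) {
              ++nfix;
              if (traj[mtr] == wt) ++nsame;
            }
            mpos[i] ^= (1u << j);
          }
        }
        nmut += ntot;
        vsum += nfix / (double)ntot;
        if (nfix > 0) {
          rbsum += nsame / (double)nfix;
          ++nrb;
        }
      }
      scans(scan_row, 0) = gen;
      scans(scan_row, 1) = rsum / n;
      scans(scan_row, 2) = nsc ? vsum / nsc : NA_REAL;
      scans(scan_row, 3) = nrb ? rbsum / nrb : NA_REAL;
      scans(scan_row, 4) = nsc;
      scans(scan_row, 5) = nrb;
      scans(scan_row, 6) = (double)nmut;
      for (int j = 0; j < N; ++j)
        for (int i = 0; i < N; ++i) {
          int cnt = 0;
          for (int k = 0; k < n; ++k) {
            const size_t r = (size_t)k * N + i;
            if ((nz[r] >> j) & 1u & (pos[r] >> j)) ++cnt;
          }
          oij(j * N + i, scan_row) = cnt / (double)n;
        }
      ++scan_row;
    }

    if (gen == generations) break;

    // selection: fitness-proportional sampling with replacement
    double tot = 0.0;
    for (int k = 0; k < n; ++k) { tot += fit[k]; cum[k] = tot; }
    if (tot <= 0.0) {
      ++rescues;
      for (int k = 0; k < n; ++k) cum[k] = k + 1.0;
      tot = n;
    }
    for (int k = 0; k < n; ++k) {
      const double u = unif_rand() * tot;
      const int pick = (int)(std::upper_bound(cum.begin(), cum.end(), u) -
                             cum.begin());
      const int p2 = pick < n ? pick : n - 1;
      std::copy(&pos[(size_t)p2 * N], &pos[(size_t)p2 * N] + N,
                &pos2[(size_t)k * N]);
      std::copy(&nz[(size_t)p2 * N], &nz[(size_t)p2 * N] + N,
                &nz2[(size_t)k * N]);
      std::copy(&nnz[(size_t)p2 * N], &nnz[(size_t)p2 * N] + N,
                &nnz2[(size_t)k * N]);
    }
    pos.swap(pos2);
    nz.swap(nz2);
    nnz.swap(nnz2);

    // recombination: disjoint random pairs, offspring take complementary
    // halves of the rows (full-row segregation, no crossover within rows)
    if (recomb) {
      for (int k = 0; k < n; ++k) idx[k] = k;
      for (int k = n - 1; k > 0; --k) {
        const int j = (int)(unif_rand() * (k + 1));
        std::swap(idx[k], idx[j < 0 ? 0 : (j > k ? k : j)]);
      }
      for (int i = 0; i < N; ++i) rowidx[i] = i;
      const int half = N / 2;
      for (int pr = 0; pr < n; pr += 2) {
        const int a = idx[pr], b = idx[pr + 1];
        for (int i = N - 1; i > 0; --i) {
          const int j = (int)(unif_rand() * (i + 1));
          std::swap(rowidx[i], rowidx[j < 0 ? 0 : (j > i ? i : j)]);
        }
        for (int i = 0; i < N; ++i) {
          const bool fromA = std::find(rowidx.begin(), rowidx.begin() + half,
                                       i) != rowidx.begin() + half;
          const int src1 = fromA ? a : b, src2 = fromA ? b : a;
          pos2[(size_t)a * N + i] = pos[(size_t)src1 * N + i];
          nz2[(size_t)a * N + i] = nz[(size_t)src1 * N + i];
          nnz2[(size_t)a * N + i] = nnz[(size_t)src1 * N + i];
          pos2[(size_t)b * N + i] = pos[(size_t)src2 * N + i];
          nz2[(size_t)b * N + i] = nz[(size_t)src2 * N + i];
          nnz2[(size_t)b * N + i] = nnz[(size_t)src2 * N + i];
        }
      }
      pos.swap(pos2);
      nz.swap(nz2);
      nnz.swap(nnz2);
    }

    // mutation: each entry (dense) or each non-zero entry (sparse) flips
    // sign independently with probability mu/N^2 resp. mu/(c N^2);
    // realised as a binomial flip count + distinct uniform positions
    if (mu > 0) {
      if (!sparse) {
        const double Mtot = (double)n * N * N;
        const int K = (int)R::rbinom(Mtot, mu / ((double)N * N));
        std::unordered_set<long> chosen;
        while ((int)chosen.size() < K) {
          long p = (long)(unif_rand() * Mtot);
          if (p >= (long)Mtot) p = (long)Mtot - 1;
          if (!chosen.insert(p).second) continue;
          const int k = (int)(p / ((long)N * N));
          const int rem = (int)(p % ((long)N * N));
          const int i = rem % N, j = rem / N;
          pos[(size_t)k * N + i] ^= (1u << j);
        }
      } else {
        nzlist.clear();
        for (int k = 0; k < n; ++k)
          for (int i = 0; i < N; ++i) {
            uint32_t supp = nz[(size_t)k * N + i];
            while (supp) {
              const int j = __builtin_ctz(supp);
              supp &= supp - 1;
              nzlist.push_back((k * N + i) * 32 + j);
            }
          }
        const double Mtot = (double)nzlist.size();
        const double c = Mtot / ((double)n * N * N);
        const int K = (int)R::rbinom(Mtot, mu / (c * (double)N * N));
        std::unordered_set<int> chosen;
        while ((int)chosen.size() < K) {
          int p = (int)(unif_rand() * Mtot);
          if (p >= (int)Mtot) p = (int)Mtot - 1;
          if (!chosen.insert(p).second) continue;
          const int code = nzlist[p];
          pos[(size_t)(code / 32)] ^= (1u << (code % 32));
        }
      }
    }
  }

  IntegerVector final_nets((R_xlen_t)N * N * n);
  std::vector<int> wbuf((size_t)N * N);
  for (int k = 0; k < n; ++k) {
    unpack_net(&pos[(size_t)k * N], &nz[(size_t)k * N], N, wbuf.data());
    std::copy(wbuf.begin(), wbuf.end(), final_nets.begin() + (R_xlen_t)k * N * N);
  }
  return List::create(_["pergen"] = pergen, _["scans"] = scans,
                      _["oij"] = oij, _["final_networks"] = final_nets,
                      _["rescue_events"] = rescues);
}
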