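#include <Rcpp.h>
#include <cstdint>
#include <random>
#include <vector>
using namespace Rcpp;

// Sparse QUBO held as adjacency lists: for variable l, (neighbor m, coupling v).
struct Qubo {
  int n;
  std::vector<double> lin;
  std::vector<std::vector<std::pair<int, double>>> adj;
  double offset;
};

static Qubo make_qubo(int n, const NumericVector& lin, const IntegerVector& qi,
                      const IntegerVector& qj, const NumericVector& qv,
                      double offset) {
  Qubo m;
  m.n = n;
  m.lin.assign(lin.begin(), lin.end());
  m.adj.resize(n);
  for (int t = 0; t < qi.size(); ++t) {
    m.adj[qi[t]].push_back({qj[t], qv[t]});
    m.adj[qj[t]].push_back({qi[t], qv[t]});
  }
  m.offset = offset;
  return m;
}

static double eval_energy(const Qubo& m, const std::vector<uint8_t>& q) {
  double e = m.offset;
  for (int l = 0; l < m.n; ++l) {
    if (!q[l]) continue;
    e += m.lin[l];
    for (auto& pr : m.adj[l])
      if (pr.first > l && q[pr.first]) e += pr.second;
  }
  return e;
}

// Energy change of flipping bit l in state q.
static inline double flip_delta(const Qubo& m, const std::vector<uint8_t>& q,
                                int l) {
  double field = m.lin[l];
  for (auto& pr : m.adj[l])
    if (q[pr.first]) field += pr.second;
  return q[l] ? -field : field;
}

// Exhaustive ground-state search by Gray-code enumeration. Candidate states
// within loose_tol of the running minimum are kept and re-evaluated exactly,
// so incremental floating-point drift cannot corrupt the result.
// [[Rcpp::export]]
List bf_ground_cpp(int n, NumericVector lin, IntegerVector qi, IntegerVector qj,
                   NumericVector qv, double offset, double tol,
                   int max_states) {
  if (n > 30) stop("exhaustive enumeration limited to 30 variables");
  Qubo m = make_qubo(n, lin, qi, qj, qv, offset);
  std::vector<uint8_t> q(n, 0);
  double e = m.offset;
  double best = e;
  const double loose = tol > 1e-6 ? tol : 1e-6;
  std::vector<std::pair<double, std::vector<uint8_t>>> cand;
  cand.push_back({e, q});
  uint64_t total = 1ULL << n;
  for (uint64_t k = 1; k < total; ++k) {
    int l = 0;
    uint64_t x = k;
    while (!(x & 1)) { x >>= 1; ++l; }  // ctz: bit flipped at Gray step k
    e += flip_delta(m, q, l);
    q[l] ^= 1;
    if (e <= best + loose) {
      if (e < best) best = e;
      cand.push_back({eval_energy(m, q), q});
      if ((int)cand.size() > max_states)
        stop("too many near-ground states (> max_states); model is degenerate");
    }
  }
  double exact_best = cand[0].first;
  for (auto& c : cand) exact_best = std::min(exact_best, c.first);
  std::vector<int> keep;
  for (int i = 0; i < (int)cand.size(); ++i)
    if (cand[i].first <= exact_best + tol) keep.push_back(i);
  IntegerMatrix states(keep.size(), n);
  NumericVector energies(keep.size());
  for (int r = 0; r < (int)keep.size(); ++r) {
    energies[r] = cand[keep[r]].first;
    for (int c = 0; c < n; ++c) states(r, c) = cand[keep[r]].second[c];
  }
  return List::create(_["energy"] = exact_best, _["states"] = states,
                      _["energies"] = energies);
}

// Evaluate the model on rows of a 0/1 matrix.
// [[Rcpp::export]]
NumericVector qubo_eval_cpp(int n, NumericVector lin, IntegerVector qi,
                            IntegerVector qj, NumericVector qv, double offset,
                            IntegerMatrix bits) {
  Qubo m = make_qubo(n, lin, qi, qj, qv, offset);
  NumericVector out(bits.nrow());
  std::vector<uint8_t> q(n);
  for (int r = 0; r < bits.nrow(); ++r) {
    for (int c = 0; c < n; ++c) q[c] = (uint8_t)bits(r, c);
    out[r] = eval_energy(m, q);
  }
  return out;
}

// Single-flip Metropolis simulated annealing, geometric inverse-temperature
// schedule beta_hot -> beta_cold, fixed variable order within a sweep.
// Returns per-run best-of-trajectory energy and state; reproducible per seed.
// [[Rcpp::export]]
List sa_cpp(int n, NumericVector lin, IntegerVector qi, IntegerVector qj,
            NumericVector qv, double offset, int n_runs, int sweeps,
            double beta_hot, double beta_cold, double seed) {
  Qubo m = make_qubo(n, lin, qi, qj, qv, offset);
  NumericVector energies(n_runs);
  IntegerMatrix states(n_runs, n);
  double ratio = (sweeps > 1) ? std::pow(beta_cold / beta_hot,
                                         1.0 / (sweeps - 1))
                              : 1.0;
  for (int run = 0; run < n_runs; ++run) {
    std::mt19937_64 rng((uint64_t)seed * 2654435761ULL + (uint64_t)run);
    std::uniform_real_distribution<double> unif(0.0, 1.0);
    std::vector<uint8_t> q(n), best_q;
    for (int l = 0; l < n; ++l) q[l] = (unif(rng) < 0.5) ? 1 : 0;
    double e = eval_energy(m, q);
    double best = e;
    best_q = q;
    double beta = beta_hot;
    for (int s = 0; s < sweeps; ++s) {
      for (int l = 0; l < n; ++l) {
        double d = flip_delta(m, q, l);
        if (d <= 0.0 || unif(rng) < std::exp(-beta * d)) {
          q[l] ^= 1;
          e += d;
          if (e < best) { best = e; best_q = q; }
        }
      }
      beta *= ratio;
    }
    energies[run] = eval_energy(m, best_q);  // exact, no incremental drift
    for (int c = 0; c < n; ++c) states(run, c) = best_q[c];
  }
  return List::create(_["energies"] = energies, _["states"] = states);
}

// Clustering loss: sum_ij (e_ij - blockmean)^2 via block sums.
// [[Rcpp::export]]
double cluster_loss_cpp(NumericMatrix e, IntegerVector a, int D) {
  int n = e.nrow();
  std::vector<double> S((size_t)D * D, 0.0);
  std::vector<double> cnt(D, 0.0);
  for (int i = 0; i < n; ++i) cnt[a[i] - 1] += 1.0;
  double tot = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      double v = e(i, j);
      tot += v * v;
      S[(size_t)(a[i] - 1) * D + (a[j] - 1)] += v;
    }
  double red = 0.0;
  for (int I = 0; I < D; ++I)
    for (int J = 0; J < D; ++J)
      red += S[(size_t)I * D + J] * S[(size_t)I * D + J] / (cnt[I] * cnt[J]);
  return tot - red;
}
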