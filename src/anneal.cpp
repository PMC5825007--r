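#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

// Simulated-annealing reserve selection with incremental score bookkeeping.
// The objective mirrors objective_value() in R:
//   cost(R) + blm * boundary(R) + sum_s spf_s * max(0, (t_s - held_s)/t_s).
// A deterministic 64-bit generator (splitmix64-seeded xorshift) keeps runs
// reproducible across platforms independent of std:: distributions.

namespace {

struct Rng {
  uint64_t s;
  explicit Rng(uint64_t seed) {
    // splitmix64 scramble so consecutive seeds give unrelated streams
    s = seed + 0x9E3779B97f4A7C15ULL;
    s = (s ^ (s >> 30)) * 0xBF58476D1CE4E5B9ULL;
    s = (s ^ (s >> 27)) * 0x94D049BB133111EBULL;
    s = s ^ (s >> 31);
    if (s == 0) s = 0x106689D45497FDB5ULL;
  }
  uint64_t next() {
    s ^= s << 13; s ^= s >> 7; s ^= s << 17;
    return s;
  }
  double unif() { return (next() >> 11) * (1.0 / 9007199254740992.0); }
  int below(int n) { return (int)(unif() * n) % n; }
};

struct Problem {
  int n_pu, n_sp;
  std::vector<double> cost, exposure, target, spf;
  std::vector<int> status;
  double blm;
  // adjacency (both directions) for boundary deltas
  std::vector<int> adj_ptr, adj_to;
  std::vector<double> adj_len;
  // amounts CSR by PU
  std::vector<int> amt_ptr, amt_sp;
  std::vector<double> amt_val;
};

struct State {
  std::vector<char> sel;
  std::vector<double> held;
  double cost, boundary, penalty;
  double score() const { return cost + boundary + penalty; }
};

double penalty_of(const Problem& p, double held, int s) {
  if (p.target[s] <= 0) return 0.0;
  double sf = (p.target[s] - held) / p.target[s];
  return sf > 0 ? p.spf[s] * sf : 0.0;
}

// full recomputation, used for initialisation and auditing
State full_state(const Problem& p, const std::vector<char>& sel) {
  State st;
  st.sel = sel;
  st.held.assign(p.n_sp, 0.0);
  st.cost = 0.0;
  double blen = 0.0;
  for (int u = 0; u < p.n_pu; ++u) {
    if (!sel[u]) continue;
    st.cost += p.cost[u];
    blen += p.exposure[u];
    for (int k = p.amt_ptr[u]; k < p.amt_ptr[u + 1]; ++k)
      st.held[p.amt_sp[k]] += p.amt_val[k];
    for (int k = p.adj_ptr[u]; k < p.adj_ptr[u + 1]; ++k)
      if (!sel[p.adj_to[k]]) blen += p.adj_len[k];
  }
  st.boundary = p.blm * blen;
  st.penalty = 0.0;
  for (int s = 0; s < p.n_sp; ++s) st.penalty += penalty_of(p, st.held[s], s);
  return st;
}

// score change from flipping PU u, without applying it
double flip_delta(const Problem& p, const State& st, int u) {
  double sign = st.sel[u] ? -1.0 : 1.0;
  double d = sign * p.cost[u];
  double dblen = sign * p.exposure[u];
  for (int k = p.adj_ptr[u]; k < p.adj_ptr[u + 1]; ++k) {
    int v = p.adj_to[k];
    // when adding u: edge to unselected v becomes boundary (+), edge to
    // selected v stops being boundary (-); reversed when removing
    dblen += (st.sel[v] ? -1.0 : 1.0) * sign * p.adj_len[k];
  }
  d += p.blm * dblen;
  for (int k = p.amt_ptr[u]; k < p.amt_ptr[u + 1]; ++k) {
    int s = p.amt_sp[k];
    double h_new = st.held[s] + sign * p.amt_val[k];
    d += penalty_of(p, h_new, s) - penalty_of(p, st.held[s], s);
  }
  return d;
}

void apply_flip(const Problem& p, State& st, int u, double delta_boundary_term) {
  double sign = st.sel[u] ? -1.0 : 1.0;
  st.cost += sign * p.cost[u];
  double dblen = sign * p.exposure[u];
  for (int k = p.adj_ptr[u]; k < p.adj_ptr[u + 1]; ++k) {
    dblen += (st.sel[p.adj_to[k]] ? -1.0 : 1.0) * sign * p.adj_len[k];
  }
  st.boundary += p.blm * dblen;
  for (int k = p.amt_ptr[u]; k < p.amt_ptr[u + 1]; ++k) {
    int s = p.amt_sp[k];
    double h_new = st.held[s] + sign * p.amt_val[k];
    st.penalty += penalty_of(p, h_new, s) - penalty_of(p, st.held[s], s);
    st.held[s] = h_new;
  }
  st.sel[u] = !st.sel[u];
  (void)delta_boundary_term;
}

Problem build_problem(int n_pu, NumericVector cost, IntegerVector status,
                      double blm, IntegerVector edge_a, IntegerVector edge_b,
                      NumericVector edge_len, NumericVector exposure,
                      IntegerVector amt_ptr, IntegerVector amt_sp,
                      NumericVector amt_val, NumericVector target,
                      NumericVector spf) {
  Problem p;
  p.n_pu = n_pu;
  p.n_sp = target.size();
  p.cost.assign(cost.begin(), cost.end());
  p.status.assign(status.begin(), status.end());
  p.exposure.assign(exposure.begin(), exposure.end());
  p.target.assign(target.begin(), target.end());
  p.spf.assign(spf.begin(), spf.end());
  p.blm = blm;
  std::vector<int> deg(n_pu, 0);
  int ne = edge_a.size();
  for (int e = 0; e < ne; ++e) { deg[edge_a[e]]++; deg[edge_b[e]]++; }
  p.adj_ptr.assign(n_pu + 1, 0);
  for (int u = 0; u < n_pu; ++u) p.adj_ptr[u + 1] = p.adj_ptr[u] + deg[u];
  p.adj_to.resize(p.adj_ptr[n_pu]);
  p.adj_len.resize(p.adj_ptr[n_pu]);
  std::vector<int> fill(n_pu, 0);
  for (int e = 0; e < ne; ++e) {
    int a = edge_a[e], b = edge_b[e];
    p.adj_to[p.adj_ptr[a] + fill[a]] = b;
    p.adj_len[p.adj_ptr[a] + fill[a]++] = edge_len[e];
    p.adj_to[p.adj_ptr[b] + fill[b]] = a;
    p.adj_len[p.adj_ptr[b] + fill[b]++] = edge_len[e];
  }
  p.amt_ptr.assign(amt_ptr.begin(), amt_ptr.end());
  p.amt_sp.assign(amt_sp.begin(), amt_sp.end());
  p.amt_val.assign(amt_val.begin(), amt_val.end());
  return p;
}

} // namespace

// [[Rcpp::export(name = ".anneal_core")]]
List anneal_core(int n_pu, NumericVector cost, IntegerVector status,
                 double blm, IntegerVector edge_a, IntegerVector edge_b,
                 NumericVector edge_len, NumericVector exposure,
                 IntegerVector amt_ptr, IntegerVector amt_sp,
                 NumericVector amt_val, NumericVector target,
                 NumericVector spf, int n_iter, double t_init,
                 double cooling, int cool_every, double init_prob,
                 double seed, bool audit) {
  Problem p = build_problem(n_pu, cost, status, blm, edge_a, edge_b, edge_len,
                            exposure, amt_ptr, amt_sp, amt_val, target, spf);
  Rng rng((uint64_t)seed);

  std::vector<int> avail;
  std::vector<char> sel(n_pu, 0);
  for (int u = 0; u < n_pu; ++u) {
    if (p.status[u] == 2) sel[u] = 1;
    else if (p.status[u] == 0) {
      avail.push_back(u);
      if (rng.unif() < init_prob) sel[u] = 1;
    }
  }
  State st = full_state(p, sel);

  double max_rel_err = 0.0;
  long n_accepted = 0;

  if (!avail.empty()) {
    // adaptive initial temperature: spread of |delta| over probe flips
    double T = t_init;
    if (T <= 0) {
      int n_probe = 100;
      double sum = 0, sum2 = 0;
      for (int i = 0; i < n_probe; ++i) {
        double d = flip_delta(p, st, avail[rng.below((int)avail.size())]);
        sum += std::fabs(d); sum2 += d * d;
      }
      double mean = sum / n_probe;
      double var = sum2 / n_probe - mean * mean;
      T = std::sqrt(var > 0 ? var : 0) + mean;
      if (T <= 0) T = 1.0;
    }

    for (int it = 0; it < n_iter; ++it) {
      int u = avail[rng.below((int)avail.size())];
      double d = flip_delta(p, st, u);
      if (d <= 0 || rng.unif() < std::exp(-d / T)) {
        double before = st.score();
        apply_flip(p, st, u, 0);
        ++n_accepted;
        if (audit) {
          double inc = st.score();
          State chk = full_state(p, st.sel);
          double ref = chk.score();
          double rel = std::fabs(inc - ref) /
            std::max(1.0, std::fabs(ref));
          if (rel > max_rel_err) max_rel_err = rel;
        } else {
          (void)before;
        }
      }
      if (cool_every > 0 && (it + 1) % cool_every == 0) T *= cooling;
    }

    // iterative-improvement finish: greedy single-flip sweeps
    bool improved = true;
    while (improved) {
      improved = false;
      for (size_t i = 0; i < avail.size(); ++i) {
        int u = avail[i];
        double d = flip_delta(p, st, u);
        if (d < -1e-12) {
          apply_flip(p, st, u, 0);
          improved = true;
        }
      }
    }
  }

  // re-derive the final score from scratch so returned values never carry
  // accumulated roundoff
  State fin = full_state(p, st.sel);
  LogicalVector out_sel(n_pu);
  for (int u = 0; u < n_pu; ++u) out_sel[u] = st.sel[u] != 0;
  return List::create(
    _["selected"] = out_sel,
    _["objective"] = fin.score(),
    _["n_accepted"] = (double)n_accepted,
    _["max_rel_err"] = max_rel_err);
}
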