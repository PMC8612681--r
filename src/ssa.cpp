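// Exact direct-method Gillespie simulation of a mass-action CRN on copy
// numbers, with incremental propensity updates via a species->reaction
// dependency graph. RNG is a local mt19937_64 so trajectories depend only on
// the seed argument, not on R's RNG state.

#include <Rcpp.h>
#include <random>
#include <vector>
using namespace Rcpp;

// [[Rcpp::export]]
NumericMatrix ssa_core(NumericVector n0, IntegerVector i1, IntegerVector i2,
                       NumericVector c_rate, NumericMatrix S,
                       NumericVector times, int seed) {
  const int ns = n0.size();
  const int m = c_rate.size();
  const int nt = times.size();

  std::vector<double> n(n0.begin(), n0.end());
  NumericMatrix out(nt, ns);

  // stoichiometry as sparse per-reaction change lists
  std::vector<std::vector<std::pair<int, double>>> delta(m);
  std::vector<std::vector<int>> dep(ns); // species -> reactions to refresh
  for (int j = 0; j < m; ++j) {
    for (int i = 0; i < ns; ++i) {
      double s = S(i, j);
      if (s != 0.0) delta[j].push_back({i, s});
    }
    dep[i1[j]].push_back(j);
    if (i2[j] >= 0 && i2[j] != i1[j]) dep[i2[j]].push_back(j);
  }

  auto prop = [&](int j) -> double {
    double a = c_rate[j] * n[i1[j]];
    if (i2[j] >= 0) {
      if (i2[j] == i1[j]) a = c_rate[j] * n[i1[j]] * (n[i1[j]] - 1.0) / 2.0;
      else a *= n[i2[j]];
    }
    return a > 0.0 ? a : 0.0;
  };

  std::vector<double> a(m);
  double atot = 0.0;
  for (int j = 0; j < m; ++j) { a[j] = prop(j); atot += a[j]; }

  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 2654435761u + 1u);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  double t = 0.0;
  int g = 0;
  long long resync = 0;
  const double tend = times[nt - 1];

  while (true) {
    if (atot <= 1e-300) { // zero total propensity: clean early termination
      for (; g < nt; ++g)
        for (int i = 0; i < ns; ++i) out(g, i) = n[i];
      break;
    }
    double dt = -std::log(std::max(U(rng), 1e-300)) / atot;
    double tnext = t + dt;
    while (g < nt && times[g] <= tnext) {
      for (int i = 0; i < ns; ++i) out(g, i) = n[i];
      ++g;
    }
    if (g >= nt || tnext > tend) {
      for (; g < nt; ++g)
        for (int i = 0; i < ns; ++i) out(g, i) = n[i];
      break;
    }
    t = tnext;
    // pick reaction
    double r = U(rng) * atot, acc = 0.0;
    int j = m - 1;
    for (int k = 0; k < m; ++k) {
      acc += a[k];
      if (r <= acc) { j = k; break; }
    }
    for (auto& pr : delta[j]) n[pr.first] += pr.second;
    // refresh dependent propensities
    for (auto& pr : delta[j]) {
      for (int k : dep[pr.first]) {
        atot -= a[k];
        a[k] = prop(k);
        atot += a[k];
      }
    }
    if (++resync % 100000 == 0) { // guard against drift
      atot = 0.0;
      for (int k = 0; k < m; ++k) { a[k] = prop(k); atot += a[k]; }
    }
  }
  return out;
}
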