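// Stochastic reversible step-growth assembly of one monomer type.
//
// Fibrils are a multiset of integer lengths. End-to-end joining of fibrils
// i, j has propensity k_join * a(t)^m_arm * (L_i * L_j)^(-gamma) (k_join
// already contains the per-monomer concentration scaling); every internal
// bond breaks at rate k_break * d(t) * (1 - a(t))^theta_break. The arming
// fraction a(t) and disarm hazard d(t) are piecewise-constant on a supplied
// grid; within each interval the simulation is an exact SSA.

#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List assembly_core(int n_monomers, double dimer_frac,
                   NumericVector tgrid, NumericVector a_vals,
                   NumericVector d_vals,
                   double k_join, double gamma_, double m_arm,
                   double theta_break, double k_break, double k_frag0,
                   NumericVector checkpoint_times, int seed) {
  std::mt19937_64 rng(static_cast<uint64_t>(seed) * 6364136223846793005ULL + 7u);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  std::vector<int> L;
  int ndim = (int)std::floor(dimer_frac * n_monomers / 2.0 + 0.5);
  for (int i = 0; i < ndim; ++i) L.push_back(2);
  for (int i = 0; i < n_monomers - 2 * ndim; ++i) L.push_back(1);

  auto wof = [&](int len) { return std::pow((double)len, -gamma_); };
  double sumw = 0.0, sumw2 = 0.0;
  long nbonds = 0;
  for (int len : L) { double w = wof(len); sumw += w; sumw2 += w * w; }
  for (int len : L) nbonds += len - 1;

  const int K = a_vals.size();
  const int nc = checkpoint_times.size();
  List snaps(nc);
  int ci = 0;
  double t = 0.0;
  long long steps = 0;

  auto snapshot_due = [&](double tnow) {
    while (ci < nc && checkpoint_times[ci] <= tnow) {
      snaps[ci] = IntegerVector(L.begin(), L.end());
      ++ci;
    }
  };
  snapshot_due(0.0);

  for (int k = 0; k < K; ++k) {
    double tend = tgrid[k + 1];
    double a = a_vals[k], d = d_vals[k];
    double joinfac = k_join * std::pow(a, m_arm);
    double breakfac = k_break * d * std::pow(std::max(0.0, 1.0 - a), theta_break)
                      + k_frag0;
    while (true) {
      double Ajoin = joinfac * (sumw * sumw - sumw2) / 2.0;
      if (Ajoin < 0) Ajoin = 0;
      double Abreak = breakfac * (double)nbonds;
      double Atot = Ajoin + Abreak;
      if (Atot <= 1e-300) { t = tend; break; }
      double dt = -std::log(std::max(U(rng), 1e-300)) / Atot;
      if (t + dt > tend) { snapshot_due(tend); t = tend; break; }
      t += dt;
      snapshot_due(t);
      if (++steps > 200000000LL) stop("assembly event-count overflow");
      if (U(rng) * Atot < Ajoin) {
        // join: sample i, j with probability proportional to w
        int nf = (int)L.size();
        if (nf < 2) continue;
        // rejection sampling: i, j independently proportional to w,
        // rejected on collision, gives P(i,j) proportional to w_i * w_j
        int i = -1, j = -1;
        for (int tries = 0; tries < 1000; ++tries) {
          double r1 = U(rng) * sumw, acc = 0.0;
          i = nf - 1;
          for (int q = 0; q < nf; ++q) { acc += wof(L[q]); if (r1 <= acc) { i = q; break; } }
          double r2 = U(rng) * sumw; acc = 0.0; j = nf - 1;
          for (int q = 0; q < nf; ++q) { acc += wof(L[q]); if (r2 <= acc) { j = q; break; } }
          if (i != j) break;
        }
        if (i == j || i < 0) continue;
        double wi = wof(L[i]), wj = wof(L[j]);
        int Lnew = L[i] + L[j];
        double wn = wof(Lnew);
        sumw += wn - wi - wj;
        sumw2 += wn * wn - wi * wi - wj * wj;
        nbonds += 1;
        L[i] = Lnew;
        L[j] = L.back(); L.pop_back();
      } else {
        // break: pick a fibril proportional to its internal bond count
        double r1 = U(rng) * (double)nbonds, acc = 0.0;
        int i = -1;
        int nf = (int)L.size();
        for (int q = 0; q < nf; ++q) {
          acc += (double)(L[q] - 1);
          if (r1 <= acc) { i = q; break; }
        }
        if (i < 0) continue;
        int len = L[i];
        std::uniform_int_distribution<int> cut(1, len - 1);
        int left = cut(rng);
        int right = len - left;
        double wold = wof(len), wl = wof(left), wr = wof(right);
        sumw += wl + wr - wold;
        sumw2 += wl * wl + wr * wr - wold * wold;
        nbonds -= 1;
        L[i] = left;
        L.push_back(right);
      }
    }
    snapshot_due(t);
  }
  // monomer conservation check
  long total = 0;
  for (int len : L) total += len;
  if (total != n_monomers) stop("monomer conservation violated in assembly");
  while (ci < nc) { snaps[ci] = IntegerVector(L.begin(), L.end()); ++ci; }
  return snaps;
}
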