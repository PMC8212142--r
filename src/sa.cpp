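#include <Rcpp.h>
#include <random>
#include <cmath>

using namespace Rcpp;

// Simulated annealing on an Ising problem with a linear inverse-temperature
// schedule and sequential single-spin Metropolis sweeps.
//
// h:    length-D local fields.
// Jsym: D x D symmetric coupling matrix (upper + lower, zero diagonal).
// One mt19937 stream per call; draws are consumed in (read, spin) order:
// D uniforms to initialize a read, then one uniform per proposed flip.
// [[Rcpp::export(name = ".sa_anneal")]]
IntegerMatrix sa_anneal(NumericVector h, NumericMatrix Jsym, int n_reads,
                        int n_sweeps, double beta_initial, double beta_final,
                        int seed) {
  const int D = h.size();
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_real_distribution<double> unif(0.0, 1.0);

  IntegerMatrix out(n_reads, D);
  std::vector<int> s(D);
  std::vector<double> f(D); // local field cache: f_i = h_i + sum_j J_ij s_j

  for (int r = 0; r < n_reads; ++r) {
    for (int i = 0; i < D; ++i) s[i] = unif(rng) < 0.5 ? -1 : 1;
    for (int i = 0; i < D; ++i) {
      double acc = h[i];
      for (int j = 0; j < D; ++j) acc += Jsym(i, j) * s[j];
      f[i] = acc;
    }
    for (int t = 0; t < n_sweeps; ++t) {
      double beta = n_sweeps > 1
        ? beta_initial + (beta_final - beta_initial) * t / (n_sweeps - 1)
        : beta_initial;
      for (int i = 0; i < D; ++i) {
        double dE = -2.0 * s[i] * f[i];
        double u = unif(rng);
        if (dE <= 0.0 || u < std::exp(-beta * dE)) {
          s[i] = -s[i];
          double step = 2.0 * s[i];
          for (int j = 0; j < D; ++j) f[j] += step * Jsym(j, i);
          f[i] -= step * Jsym(i, i); // no self-coupling (diag is zero anyway)
        }
      }
    }
    for (int i = 0; i < D; ++i) out(r, i) = s[i];
  }
  return out;
}
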