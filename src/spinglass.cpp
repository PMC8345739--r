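#include <Rcpp.h>
using namespace Rcpp;

// Single-spin-flip Metropolis annealing of the signed Potts Hamiltonian
//   H(sigma) = -sum_{i<j} A_ij * delta(sigma_i, sigma_j)
// where A is the precomputed signed coupling matrix (observed weight minus
// the per-sign-layer null model). Geometric cooling from t_start to t_end;
// returns the lowest-energy state visited. Uses R's RNG so results are
// reproducible under set.seed().

static double state_energy(const NumericMatrix& A, const IntegerVector& s) {
  int n = s.size();
  double h = 0.0;
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (s[i] == s[j]) h -= A(i, j);
  return h;
}

// [[Rcpp::export(name = ".anneal_cpp")]]
List anneal_cpp(NumericMatrix A, int q_max, double t_start, double t_end,
                double cooling, int sweeps_per_temp) {
  int n = A.nrow();
  IntegerVector s(n);
  for (int i = 0; i < n; ++i)
    s[i] = (int)(unif_rand() * q_max);
  double h = state_energy(A, s);
  IntegerVector best = clone(s);
  double best_h = h;

  for (double t = t_start; t >= t_end; t *= cooling) {
    for (int sweep = 0; sweep < sweeps_per_temp; ++sweep) {
      for (int step = 0; step < n; ++step) {
        int i = (int)(unif_rand() * n);
        int snew = (int)(unif_rand() * q_max);
        if (snew == s[i]) continue;
        double dh = 0.0;
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          if (s[j] == s[i]) dh += A(i, j);      // leaving community of i
          if (s[j] == snew) dh -= A(i, j);      // joining community of snew
        }
        if (dh <= 0.0 || unif_rand() < std::exp(-dh / t)) {
          s[i] = snew;
          h += dh;
          if (h < best_h - 1e-12) {
            best_h = h;
            best = clone(s);
          }
        }
      }
    }
  }
  return List::create(_["assignment"] = best, _["energy"] = best_h);
}
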