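#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Canonical Metropolis sampling of 1D hard rods on a ring.
//
// Positions are kept sorted on an unwrapped line: neighbours of rod i
// are i-1 and i+1, with periodic images L_box away at the ends.  A
// single-particle displacement is accepted iff the rod stays strictly
// between its neighbours' cores, which for hard rods is the full
// Metropolis rule (rods cannot pass each other).  Coordinates are
// wrapped into [0, L_box) only when a configuration is stored.
//
// Uses R's RNG so runs are reproducible under set.seed().

// [[Rcpp::export]]
NumericMatrix tonks_mc_run(NumericVector start, double sigma, double L_box,
                           int n_sweeps, int burn_in, int thin, double delta) {
  const int N = start.size();
  std::vector<double> x(start.begin(), start.end());
  int n_keep = (n_sweeps > burn_in) ? (n_sweeps - burn_in) / thin : 0;
  if (n_keep < 0) n_keep = 0;
  NumericMatrix out(n_keep, N);
  int stored = 0;
  for (int s = 1; s <= n_sweeps; ++s) {
    for (int m = 0; m < N; ++m) {
      int i = (int)(unif_rand() * N);
      if (i >= N) i = N - 1;
      double xi = x[i] + delta * (2.0 * unif_rand() - 1.0);
      if (N == 1) { x[i] = xi; continue; }
      double xl = (i > 0) ? x[i - 1] : x[N - 1] - L_box;
      double xr = (i < N - 1) ? x[i + 1] : x[0] + L_box;
      if (xi >= xl + sigma && xi <= xr - sigma) x[i] = xi;
    }
    if (s > burn_in && (s - burn_in) % thin == 0 && stored < n_keep) {
      std::vector<double> w(N);
      for (int j = 0; j < N; ++j) {
        double p = x[j] - L_box * std::floor(x[j] / L_box);
        if (p >= L_box) p -= L_box;
        w[j] = p;
      }
      std::sort(w.begin(), w.end());
      for (int j = 0; j < N; ++j) out(stored, j) = w[j];
      ++stored;
    }
  }
  return out;
}
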