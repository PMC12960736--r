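#include <Rcpp.h>
using namespace Rcpp;

// Single-chain single-site Gibbs sampler for a {0,1} Ising model.
// Uses R's RNG so draws are reproducible under set.seed().
// [[Rcpp::export]]
IntegerMatrix gibbs_sample_cpp(NumericVector tau, NumericMatrix omega,
                               int n, int burnin, int thin) {
  int p = tau.size();
  if (omega.nrow() != p || omega.ncol() != p)
    stop("omega dimensions do not match tau");
  if (thin < 1) stop("thin must be >= 1");
  IntegerMatrix out(n, p);
  std::vector<int> x(p, 0);
  RNGScope scope;
  // random initial state from the independent-thresholds distribution
  for (int j = 0; j < p; ++j)
    x[j] = (unif_rand() < 1.0 / (1.0 + std::exp(-tau[j]))) ? 1 : 0;
  long total = (long)burnin + (long)n * thin;
  long kept = 0;
  for (long s = 0; s < total; ++s) {
    for (int j = 0; j < p; ++j) {
      double eta = tau[j];
      for (int k = 0; k < p; ++k)
        if (x[k]) eta += omega(k, j);
      // diagonal is zero so including k==j is harmless, but skip anyway
      if (x[j]) eta -= omega(j, j);
      double pr = 1.0 / (1.0 + std::exp(-eta));
      x[j] = (unif_rand() < pr) ? 1 : 0;
    }
    if (s >= burnin && ((s - burnin) % thin == (thin - 1))) {
      for (int j = 0; j < p; ++j) out(kept, j) = x[j];
      ++kept;
      if (kept == n) break;
    }
  }
  return out;
}
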