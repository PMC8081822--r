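#include <Rcpp.h>
using namespace Rcpp;

// Resampling kernels for the Monte Carlo null and the baseline bootstrap.
// Both consume R's RNG stream (via R_unif_index, the same unbiased index
// sampler base R uses), so draws are reproducible under set.seed() and do
// not disturb callers that manage .Random.seed themselves.

// Sums of a home-amount vector and a total-amount vector over `m` uniform
// without-replacement subsamples of size `n`, via partial Fisher-Yates.
// [[Rcpp::export]]
List mc_subsample_sums(NumericVector home, NumericVector total, int n, int m) {
  int npop = home.size();
  if (total.size() != npop)
    stop("home and total amount vectors must have equal length");
  if (n < 0 || n > npop)
    stop("subsample size must lie in [0, population size]");
  NumericVector num(m), den(m);
  std::vector<int> pool(npop);
  for (int d = 0; d < m; ++d) {
    for (int i = 0; i < npop; ++i) pool[i] = i;
    double s_home = 0.0, s_tot = 0.0;
    for (int j = 0; j < n; ++j) {
      int k = j + (int) R_unif_index((double)(npop - j));
      std::swap(pool[j], pool[k]);
      s_home += home[pool[j]];
      s_tot  += total[pool[j]];
    }
    num[d] = s_home;
    den[d] = s_tot;
  }
  return List::create(_["num"] = num, _["den"] = den);
}

// Sums over `b` with-replacement resamples of the full population
// (ordinary nonparametric bootstrap of a ratio-of-sums statistic).
// [[Rcpp::export]]
List boot_resample_sums(NumericVector home, NumericVector total, int b) {
  int npop = home.size();
  if (total.size() != npop)
    stop("home and total amount vectors must have equal length");
  NumericVector num(b), den(b);
  for (int r = 0; r < b; ++r) {
    double s_home = 0.0, s_tot = 0.0;
    for (int i = 0; i < npop; ++i) {
      int k = (int) R_unif_index((double) npop);
      s_home += home[k];
      s_tot  += total[k];
    }
    num[r] = s_home;
    den[r] = s_tot;
  }
  return List::create(_["num"] = num, _["den"] = den);
}
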