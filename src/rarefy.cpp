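#include <Rcpp.h>
using namespace Rcpp;

// Exact multivariate-hypergeometric subsample of `depth` reads from integer
// category counts, drawn category by category from the conditional
// hypergeometric distributions. Uses R's RNG stream, so draws are
// reproducible under set.seed(). O(#categories) time and memory, independent
// of the library size, which can reach several 1e7 reads.
// [[Rcpp::export(name = ".rarefy_hyper_cpp")]]
NumericVector rarefy_hyper(NumericVector counts, double depth) {
  R_xlen_t s = counts.size();
  NumericVector out(s);
  long double remaining = 0.0;
  for (R_xlen_t i = 0; i < s; ++i) remaining += counts[i];
  double m = depth;
  for (R_xlen_t i = 0; i < s && m > 0; ++i) {
    double ni = counts[i];
    remaining -= ni;
    double k;
    if (remaining <= 0) {
      k = m; // last non-empty category takes the rest
    } else {
      k = ::Rf_rhyper(ni, (double)remaining, m);
    }
    out[i] = k;
    m -= k;
  }
  return out;
}
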