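#include <Rcpp.h>
using namespace Rcpp;

// Log-likelihood of one replicate time course over every grid combination.
//
// counts, coverage: methylated counts and coverages per timepoint (NA-free).
// bank: ncombo x T matrix of expected methylation fractions.
// gamma: beta-binomial over-dispersion; gamma <= 0 selects the binomial model.
//
// Returns a vector of length ncombo with
//   ll_j = sum_t log pmf(counts[t] | coverage[t], bank(j, t)).
//
// Exploits alpha + beta = s (constant in the combination) so only two lgamma
// evaluations per (combo, timepoint) depend on the data.
// [[Rcpp::export(name = ".bb_loglik_grid")]]
NumericVector bb_loglik_grid(IntegerVector counts, IntegerVector coverage,
                             NumericMatrix bank, double gamma) {
  const int T = counts.size();
  if (coverage.size() != T || bank.ncol() != T)
    stop("counts, coverage and bank timepoints must align");
  const int ncombo = bank.nrow();
  NumericVector ll(ncombo, 0.0);
  const double pmin = 1e-12, pmax = 1.0 - 1e-12;

  if (gamma <= 0.0) { // binomial
    for (int t = 0; t < T; ++t) {
      const double c = counts[t], n = coverage[t];
      const double lch = R::lchoose(n, c);
      for (int j = 0; j < ncombo; ++j) {
        double p = bank(j, t);
        if (p < pmin) p = pmin;
        if (p > pmax) p = pmax;
        ll[j] += lch + c * std::log(p) + (n - c) * std::log1p(-p);
      }
    }
    return ll;
  }

  const double s = 1.0 / gamma - 1.0;
  for (int t = 0; t < T; ++t) {
    const double c = counts[t], n = coverage[t];
    // lbeta(c + a, n - c + b) - lbeta(a, b) with a + b = s:
    //   lgamma(c + a) + lgamma(n - c + b) - lgamma(n + s)
    // - lgamma(a) - lgamma(b) + lgamma(s)
    const double konst = R::lchoose(n, c) - R::lgammafn(n + s) +
      R::lgammafn(s);
    for (int j = 0; j < ncombo; ++j) {
      double p = bank(j, t);
      if (p < pmin) p = pmin;
      if (p > pmax) p = pmax;
      const double a = p * s, b = s - a;
      ll[j] += konst + R::lgammafn(c + a) + R::lgammafn(n - c + b) -
        R::lgammafn(a) - R::lgammafn(b);
    }
  }
  return ll;
}
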