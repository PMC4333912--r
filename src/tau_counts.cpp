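#include <Rcpp.h>
using namespace Rcpp;

// Exact pair counts for Kendall's tau-b: concordant (C), discordant (D),
// and within-vector tie counts (n1, n2) over all n(n-1)/2 case pairs.
// Counts are whole numbers held in doubles (exact below 2^53).
// [[Rcpp::export(name = ".tau_counts_pairs")]]
List tau_counts_pairs(NumericVector x, NumericVector y) {
  const R_xlen_t n = x.size();
  double C = 0, D = 0, n1 = 0, n2 = 0;
  for (R_xlen_t i = 0; i < n - 1; ++i) {
    const double xi = x[i], yi = y[i];
    for (R_xlen_t j = i + 1; j < n; ++j) {
      const double dx = x[j] - xi, dy = y[j] - yi;
      if (dx == 0) ++n1;
      if (dy == 0) ++n2;
      if (dx == 0 || dy == 0) continue;
      if ((dx > 0) == (dy > 0)) ++C; else ++D;
    }
  }
  const double n0 = static_cast<double>(n) * (n - 1) / 2.0;
  return List::create(_["C"] = C, _["D"] = D, _["n0"] = n0,
                      _["n1"] = n1, _["n2"] = n2);
}
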