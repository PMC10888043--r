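// Harrell concordance pair counting. Comparable pairs: (i, j) with E_i = 1
// and T_i < T_j, or E_i = 1, E_j = 0, T_i = T_j; risk ties count 1/2.

#include <Rcpp.h>

// [[Rcpp::export]]
Rcpp::NumericVector cpp_cindex_counts(const Rcpp::NumericVector& time,
                                      const Rcpp::IntegerVector& event,
                                      const Rcpp::NumericVector& risk) {
  const int n = time.size();
  double num = 0.0, den = 0.0;
  for (int i = 0; i < n; ++i) {
    if (event[i] != 1) continue;
    for (int j = 0; j < n; ++j) {
      if (i == j) continue;
      const bool comparable = (time[i] < time[j]) ||
        (time[i] == time[j] && event[j] == 0);
      if (!comparable) continue;
      den += 1.0;
      if (risk[i] > risk[j]) num += 1.0;
      else if (risk[i] == risk[j]) num += 0.5;
    }
  }
  return Rcpp::NumericVector::create(num, den);
}
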