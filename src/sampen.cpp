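#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Sample entropy by direct pair counting (Richman & Moorman convention):
// over the N - m templates that admit an (m+1)-th continuation, count pairs
// i < j whose m-length templates match within Chebyshev tolerance r (B) and
// whose (m+1)-length templates also match (A). Self-matches are excluded by
// construction. Returns -log(A/B); the degenerate cases (B == 0, A == 0)
// are resolved by the R wrapper.
// [[Rcpp::export]]
List sampen_counts(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nt = n - m;  // number of templates with a continuation
  double A = 0.0, B = 0.0;
  for (int i = 0; i < nt - 1; ++i) {
    for (int j = i + 1; j < nt; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        double dk = std::fabs(x[i + k] - x[j + k]);
        if (dk > d) d = dk;
      }
      if (d <= r) {
        B += 1.0;
        double dm = std::fabs(x[i + m] - x[j + m]);
        if (dm <= r) A += 1.0;
      }
    }
  }
  return List::create(Named("A") = A, Named("B") = B);
}
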