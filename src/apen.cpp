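#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// ApEn = Phi_m(r) - Phi_{m+1}(r): Chebyshev distance, strict d < r,
// self-matches included. Both correlation sums are accumulated in one pass
// over the pair grid; the m-length prefix distance is reused for the
// (m+1)-length comparison.
// [[Rcpp::export]]
double apen_cpp(NumericVector x, int m, double r) {
  const int n = x.size();
  const int nm = n - m + 1;   // number of m-length templates
  const int nm1 = n - m;      // number of (m+1)-length templates
  if (nm1 < 1) stop("series too short for ApEn");
  std::vector<int> cm(nm, 0), cm1(nm1, 0);
  const double* xs = REAL(x);
  for (int i = 0; i < nm; ++i) {
    for (int j = i; j < nm; ++j) {
      double d = 0.0;
      for (int k = 0; k < m; ++k) {
        const double t = std::fabs(xs[i + k] - xs[j + k]);
        d = (t > d) ? t : d;
      }
      if (d < r) {
        ++cm[i];
        if (j > i) ++cm[j];
        if (i < nm1 && j < nm1) {
          const double t = std::fabs(xs[i + m] - xs[j + m]);
          if ((t > d ? t : d) < r) {
            ++cm1[i];
            if (j > i) ++cm1[j];
          }
        }
      }
    }
  }
  double phi_m = 0.0, phi_m1 = 0.0;
  for (int i = 0; i < nm; ++i)
    phi_m += std::log(static_cast<double>(cm[i]) / nm);
  phi_m /= nm;
  for (int i = 0; i < nm1; ++i)
    phi_m1 += std::log(static_cast<double>(cm1[i]) / nm1);
  phi_m1 /= nm1;
  return phi_m - phi_m1;
}
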