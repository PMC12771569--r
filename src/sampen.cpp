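#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy, Richman & Moorman counting convention:
// templates of length m and m+1 both taken at i = 0..N-m-1 so the same
// pair set underlies both counts; Chebyshev distance, self-matches
// excluded. Returns NA when either count is zero (degenerate input).
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r) {
  int n = x.size();
  int nt = n - m;            // number of templates (both lengths)
  if (nt < 2) return NA_REAL;
  double A = 0.0, B = 0.0;
  const double *p = x.begin();
  if (m == 2) {              // unrolled fast path (the default)
    long a = 0, b = 0;
    for (int i = 0; i < nt - 1; ++i) {
      const double xi0 = p[i], xi1 = p[i + 1], xi2 = p[i + 2];
      for (int j = i + 1; j < nt; ++j) {
        double d0 = std::fabs(xi0 - p[j]);
        double d1 = std::fabs(xi1 - p[j + 1]);
        double d = d0 > d1 ? d0 : d1;
        if (d <= r) {
          ++b;
          double d2 = std::fabs(xi2 - p[j + 2]);
          if (d2 <= r) ++a;
        }
      }
    }
    if (a == 0 || b == 0) return NA_REAL;
    return -std::log((double)a / (double)b);
  }
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
        if (dm > d) d = dm;
        if (d <= r) A += 1.0;
      }
    }
  }
  if (B == 0.0 || A == 0.0) return NA_REAL;
  return -std::log(A / B);
}
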