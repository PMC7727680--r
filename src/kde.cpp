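#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Raw 1-D kernel sums sum_i K((q - c_i)/h) for each query q, without the
// normalisation constants (applied in R, where the kernel convention lives).
// family: 0 = gaussian exp(-u^2/2), 1 = uniform 1{|u| <= 1/2},
//         2 = triangular max(0, 1 - |u|).
// [[Rcpp::export]]
NumericVector kernel_sums_1d(NumericVector queries, NumericVector centers,
                             double h, int family) {
  const int nq = queries.size(), nc = centers.size();
  NumericVector out(nq);
  for (int i = 0; i < nq; ++i) {
    const double q = queries[i];
    double s = 0.0;
    switch (family) {
    case 0:
      for (int j = 0; j < nc; ++j) {
        const double u = (q - centers[j]) / h;
        s += std::exp(-0.5 * u * u);
      }
      break;
    case 1:
      for (int j = 0; j < nc; ++j) {
        const double u = (q - centers[j]) / h;
        if (std::fabs(u) <= 0.5) s += 1.0;
      }
      break;
    default:
      for (int j = 0; j < nc; ++j) {
        const double u = std::fabs((q - centers[j]) / h);
        if (u < 1.0) s += 1.0 - u;
      }
    }
    out[i] = s;
  }
  return out;
}
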