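// In-place SGD update kernels.  A mini-batch step touches every
// parameter (the dense layer alone holds ~4e5 doubles), and doing the
// Adagrad/RMSProp/Adam arithmetic in R allocates several full-size
// temporaries per step; these kernels update the parameter and the
// optimizer state in one pass with no allocation, through raw pointers.
// Callers own the buffers and guarantee they are not shared.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
void step_adagrad_(NumericVector w, NumericVector g, NumericVector acc,
                   double lr, double eps) {
  const R_xlen_t n = w.size();
  double *pw = w.begin(), *pa = acc.begin();
  const double *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pa[i] += pg[i] * pg[i];
    pw[i] -= lr * pg[i] / (std::sqrt(pa[i]) + eps);
  }
}

// [[Rcpp::export]]
void step_rmsprop_(NumericVector w, NumericVector g, NumericVector acc,
                   double lr, double rho, double eps) {
  const R_xlen_t n = w.size();
  double *pw = w.begin(), *pa = acc.begin();
  const double *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pa[i] = rho * pa[i] + (1.0 - rho) * pg[i] * pg[i];
    pw[i] -= lr * pg[i] / (std::sqrt(pa[i]) + eps);
  }
}

// [[Rcpp::export]]
void step_adam_(NumericVector w, NumericVector g, NumericVector m,
                NumericVector v, double lr, double b1, double b2,
                double eps, double corr) {
  const R_xlen_t n = w.size();
  double *pw = w.begin(), *pm = m.begin(), *pv = v.begin();
  const double *pg = g.begin();
  for (R_xlen_t i = 0; i < n; ++i) {
    pm[i] = b1 * pm[i] + (1.0 - b1) * pg[i];
    pv[i] = b2 * pv[i] + (1.0 - b2) * pg[i] * pg[i];
    pw[i] -= lr * corr * pm[i] / (std::sqrt(pv[i]) + eps);
  }
}
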