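#include <Rcpp.h>
using namespace Rcpp;

// Weighted Gaussian-mixture response density with a uniform lapse component:
//   f(tp) = (1 - gamma) * sum_k w[k] * N(tp; te[k] + b, (w_p * te[k])^2)
//         + gamma * Unif(tp; lapse_lo, lapse_hi)
// te[k] are estimator outputs on the (flattened) measurement quadrature grid
// and w[k] the corresponding quadrature probability weights. Components
// beyond 8 SDs contribute < 1e-14 relative mass and are skipped.
// [[Rcpp::export]]
NumericVector mixture_density_cpp(NumericVector tp, NumericVector te,
                                  NumericVector w, double w_p, double b,
                                  double gamma, double lapse_lo,
                                  double lapse_hi) {
  const double inv_sqrt_2pi = 0.39894228040143268;
  const int n_tp = tp.size();
  const int n_te = te.size();
  if (te.size() != w.size()) stop("'te' and 'w' must have equal length");
  const double lapse_dens = 1.0 / (lapse_hi - lapse_lo);
  NumericVector out(n_tp);
  for (int j = 0; j < n_tp; ++j) {
    const double x = tp[j];
    double acc = 0.0;
    for (int k = 0; k < n_te; ++k) {
      const double sd = w_p * te[k];
      const double z = (x - te[k] - b) / sd;
      if (z > -8.0 && z < 8.0)
        acc += w[k] * inv_sqrt_2pi / sd * std::exp(-0.5 * z * z);
    }
    const double lap =
        (x >= lapse_lo && x <= lapse_hi) ? lapse_dens : 0.0;
    out[j] = (1.0 - gamma) * acc + gamma * lap;
  }
  return out;
}
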