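#include <Rcpp.h>
using namespace Rcpp;

// Scaled forward-backward for a 2-state HMM with precomputed log emission
// densities. Returns posterior state probabilities, expected transition
// counts, and the log-likelihood.
// [[Rcpp::export]]
List hmm_forward_backward_cpp(NumericMatrix logem, NumericMatrix trans,
                              NumericVector init) {
  const int n = logem.nrow();
  NumericMatrix alpha(n, 2), beta(n, 2), gamma(n, 2);
  NumericVector scale(n), cmax(n);

  cmax[0] = std::max(logem(0, 0), logem(0, 1));
  double a0 = init[0] * std::exp(logem(0, 0) - cmax[0]);
  double a1 = init[1] * std::exp(logem(0, 1) - cmax[0]);
  scale[0] = a0 + a1;
  alpha(0, 0) = a0 / scale[0];
  alpha(0, 1) = a1 / scale[0];

  for (int t = 1; t < n; ++t) {
    cmax[t] = std::max(logem(t, 0), logem(t, 1));
    double e0 = std::exp(logem(t, 0) - cmax[t]);
    double e1 = std::exp(logem(t, 1) - cmax[t]);
    double p0 = alpha(t - 1, 0), p1 = alpha(t - 1, 1);
    double b0 = (p0 * trans(0, 0) + p1 * trans(1, 0)) * e0;
    double b1 = (p0 * trans(0, 1) + p1 * trans(1, 1)) * e1;
    scale[t] = b0 + b1;
    alpha(t, 0) = b0 / scale[t];
    alpha(t, 1) = b1 / scale[t];
  }

  beta(n - 1, 0) = 1.0;
  beta(n - 1, 1) = 1.0;
  for (int t = n - 2; t >= 0; --t) {
    double e0 = std::exp(logem(t + 1, 0) - cmax[t + 1]) * beta(t + 1, 0);
    double e1 = std::exp(logem(t + 1, 1) - cmax[t + 1]) * beta(t + 1, 1);
    beta(t, 0) = (trans(0, 0) * e0 + trans(0, 1) * e1) / scale[t + 1];
    beta(t, 1) = (trans(1, 0) * e0 + trans(1, 1) * e1) / scale[t + 1];
  }

  double ll = 0.0;
  for (int t = 0; t < n; ++t) {
    double g0 = alpha(t, 0) * beta(t, 0);
    double g1 = alpha(t, 1) * beta(t, 1);
    double s = g0 + g1;
    gamma(t, 0) = g0 / s;
    gamma(t, 1) = g1 / s;
    ll += std::log(scale[t]) + cmax[t];
  }

  NumericMatrix xi(2, 2);
  for (int t = 0; t < n - 1; ++t) {
    double e0 = std::exp(logem(t + 1, 0) - cmax[t + 1]) * beta(t + 1, 0);
    double e1 = std::exp(logem(t + 1, 1) - cmax[t + 1]) * beta(t + 1, 1);
    xi(0, 0) += alpha(t, 0) * trans(0, 0) * e0 / scale[t + 1];
    xi(0, 1) += alpha(t, 0) * trans(0, 1) * e1 / scale[t + 1];
    xi(1, 0) += alpha(t, 1) * trans(1, 0) * e0 / scale[t + 1];
    xi(1, 1) += alpha(t, 1) * trans(1, 1) * e1 / scale[t + 1];
  }

  return List::create(_["gamma"] = gamma, _["xi"] = xi, _["loglik"] = ll);
}
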