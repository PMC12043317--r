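#include <Rcpp.h>
using namespace Rcpp;

// Euler integration of the 3-population rate dynamics driven by a
// temporally smoothed (AR(1)/Ornstein-Uhlenbeck-like) input process:
//   tau_xi dxi/dt = -xi + I + sigma * zeta
//   tau   dr/dt   = -r + alpha * [ W r + xi + Imod ]_+ ^ beta
// zeta is standard-normal white noise; in "per_step" mode (noise_mode = 0)
// one unit-variance draw is applied per Euler step, in Euler-Maruyama mode
// (noise_mode = 1) the draw is scaled by 1/sqrt(dt).
// Rates are hard-rectified at zero.  Uses R's RNG, so runs are reproducible
// from set.seed() and identical seeds freeze the noise across conditions.
// [[Rcpp::export]]
NumericMatrix noisy_rates_cpp(NumericMatrix W, NumericVector I,
                              NumericVector Imod, NumericVector r0,
                              double t_end, double dt, NumericVector tau,
                              double tau_xi, NumericVector sigma,
                              NumericVector alpha, NumericVector beta,
                              int noise_mode, int thin, double rate_bound) {
  int n = (int)std::round(t_end / dt);
  double a = dt / tau_xi;
  double zscale = (noise_mode == 1) ? 1.0 / std::sqrt(dt) : 1.0;
  int nkeep = n / thin;
  NumericMatrix out(nkeep, 4);
  double r[3], xi[3];
  for (int j = 0; j < 3; j++) { r[j] = r0[j]; xi[j] = I[j]; }
  int k = 0;
  for (int i = 0; i < n; i++) {
    double q[3];
    for (int j = 0; j < 3; j++) {
      double z = sigma[j] > 0 ? R::rnorm(0.0, 1.0) : 0.0;
      xi[j] += a * (-xi[j] + I[j] + sigma[j] * zscale * z);
    }
    for (int j = 0; j < 3; j++) {
      q[j] = xi[j] + Imod[j];
      for (int l = 0; l < 3; l++) q[j] += W(j, l) * r[l];
      if (q[j] < 0) q[j] = 0;
    }
    for (int j = 0; j < 3; j++) {
      r[j] += dt / tau[j] * (-r[j] + alpha[j] * std::pow(q[j], beta[j]));
      if (r[j] < 0) r[j] = 0;
      if (r[j] > rate_bound || !std::isfinite(r[j]))
        stop("rate divergence at t = %f s (unstable regime)", i * dt);
    }
    if ((i + 1) % thin == 0 && k < nkeep) {
      out(k, 0) = (i + 1) * dt;
      for (int j = 0; j < 3; j++) out(k, j + 1) = r[j];
      k++;
    }
  }
  return out;
}
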