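// Fixed-step RK4 integrator for the adjacency-disaggregated Kuramoto model:
//   dtheta_i/dt = omega_i + K * sum_j gamma_ij * sin(theta_j - theta_i)
// (attractive convention; `literal` flips the coupling sign). Phases are
// integrated unwrapped; wrapping happens on the R side.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline vec velocity(const mat& gamma, const vec& omega, const vec& theta,
                           double K, bool literal) {
  // sum_j g_ij sin(th_j - th_i) = cos(th_i)*(G s)_i - sin(th_i)*(G c)_i
  vec s = sin(theta), c = cos(theta);
  vec coupling = c % (gamma * s) - s % (gamma * c);
  if (literal) coupling = -coupling;
  return omega + K * coupling;
}

// [[Rcpp::export]]
arma::mat kuramoto_rk4_cpp(const arma::mat& gamma, const arma::vec& omega,
                           const arma::vec& theta0, double K, double dt,
                           int n_steps, bool literal, int thin) {
  const int n = theta0.n_elem;
  if (thin < 1) thin = 1;
  const int n_out = n_steps / thin + 1;
  mat out(n_out, n);
  vec theta = theta0;
  out.row(0) = theta.t();
  int row = 1;
  for (int step = 1; step <= n_steps; ++step) {
    vec k1 = velocity(gamma, omega, theta, K, literal);
    vec k2 = velocity(gamma, omega, theta + 0.5 * dt * k1, K, literal);
    vec k3 = velocity(gamma, omega, theta + 0.5 * dt * k2, K, literal);
    vec k4 = velocity(gamma, omega, theta + dt * k3, K, literal);
    theta += dt / 6.0 * (k1 + 2.0 * k2 + 2.0 * k3 + k4);
    if (step % thin == 0 && row < n_out) {
      out.row(row) = theta.t();
      ++row;
    }
  }
  return out;
}
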