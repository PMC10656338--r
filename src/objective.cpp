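// Maximum-likelihood discrepancy for the stable-trait + structured
// within-covariance model, Sigma = phi2 * 11' + Psi(theta). This is the inner
// loop of the Monte-Carlo study (thousands of covariance fits), hence C++.
#include <RcppArmadillo.h>

// structure codes (kept in step with R/measurement.R):
//   1 ar1_timevarying : theta = (v0, a_1..a_q, s_1..s_q), q = p - 1
//   2 ar1_stationary  : theta = (a, s), v0 = s / (1 - a^2)
//   3 compound_symmetry: theta = (v, c)
//   4 toeplitz        : theta = (v, r_1..r_q) with Psi_jk = v * r_|j-k|
static bool build_psi(const arma::vec& theta, int structure, int p,
                      arma::mat& Psi) {
  int q = p - 1;
  Psi.zeros(p, p);
  if (structure == 1) {
    if ((int)theta.n_elem != 1 + 2 * q) return false;
    Psi(0, 0) = theta(0);
    for (int k = 1; k < p; k++) {
      double a = theta(k);          // a_k
      double s = theta(q + k);      // s_k
      for (int j = 0; j < k; j++) {
        Psi(k, j) = a * Psi(k - 1, j);
        Psi(j, k) = Psi(k, j);
      }
      Psi(k, k) = a * a * Psi(k - 1, k - 1) + s;
    }
  } else if (structure == 2) {
    double a = theta(0), s = theta(1);
    if (std::abs(a) >= 1.0) return false;
    double v0 = s / (1.0 - a * a);
    for (int j = 0; j < p; j++)
      for (int k = 0; k < p; k++)
        Psi(j, k) = v0 * std::pow(a, std::abs(j - k));
  } else if (structure == 3) {
    double v = theta(0), c = theta(1);
    Psi.fill(c);
    Psi.diag().fill(v);
  } else if (structure == 4) {
    if ((int)theta.n_elem != 1 + q) return false;
    double v = theta(0);
    for (int j = 0; j < p; j++)
      for (int k = 0; k < p; k++)
        Psi(j, k) = v * ((j == k) ? 1.0 : theta(std::abs(j - k)));
  } else {
    return false;
  }
  return true;
}

// [[Rcpp::export]]
arma::mat implied_psi_cpp(const arma::vec& theta, int structure, int p) {
  arma::mat Psi;
  if (!build_psi(theta, structure, p, Psi))
    Rcpp::stop("invalid structure parameters");
  return Psi;
}

// F_ML(Sigma; S) = log det Sigma + tr(Sigma^-1 S); minimizing F_ML maximizes
// the multivariate-normal likelihood with saturated means. Parameters are
// unconstrained (negative variance estimates are allowed and flagged as
// improper solutions downstream); non-PD Sigma gets a smooth penalty that
// pushes the optimizer back into the feasible region.
// [[Rcpp::export]]
double cov_ml_objective(const arma::vec& par, const arma::mat& S,
                        int structure) {
  int p = S.n_rows;
  double phi2 = par(0);
  arma::mat Psi;
  if (!build_psi(par.subvec(1, par.n_elem - 1), structure, p, Psi))
    return 1e12;
  arma::mat Sigma = Psi + phi2 * arma::ones(p, p);
  arma::vec eval;
  arma::mat evec;
  if (!arma::eig_sym(eval, evec, Sigma)) return 1e12;
  double mineig = eval.min();
  if (mineig < 1e-10) return 1e10 + 1e6 * (1e-10 - mineig);
  double logdet = arma::accu(arma::log(eval));
  arma::mat Sinv = evec * arma::diagmat(1.0 / eval) * evec.t();
  return logdet + arma::trace(Sinv * S);
}
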