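#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

// Session-level marginal log-likelihood of the Poisson-count SCR model with a
// half-normal encounter kernel, marginalised over the discrete state space and
// with a known-sex two-class mixture.
//
// D2        J x G squared AC-detector distances (km^2)
// log_mu_a  G, log expected AC count per state-space cell (mu(g) * cell area)
// log_lam0  J x 2 baseline log encounter rates, columns (F, M)
// sigma     length-2 half-normal scale (F, M), km
// log_psi   length-2 log sex-mixture weights (F, M)
// YD2       n x G, counts %*% D2
// Ylogl0    n x 2, counts %*% log_lam0
// sex       n, 0 = F, 1 = M
// logyfact  n, sum_j lgamma(y_ij + 1)
// sex_specific  false when encounter rates are identical across sexes
// [[Rcpp::export]]
double scr_session_loglik_core(const arma::mat& D2, const arma::vec& log_mu_a,
                               const arma::mat& log_lam0, const arma::vec& sigma,
                               const arma::vec& log_psi, const arma::mat& YD2,
                               const arma::mat& Ylogl0, const arma::ivec& sex,
                               const arma::vec& logyfact, const bool sex_specific) {
  const uword G = D2.n_cols;
  const uword n = YD2.n_rows;
  const uword n_sex_eval = sex_specific ? 2 : 1;

  // S(g, c) = sum_j lambda_j(g, c): total encounter hazard for an AC in cell g
  mat S(G, 2);
  for (uword c = 0; c < n_sex_eval; ++c) {
    const double two_s2 = 2.0 * sigma(c) * sigma(c);
    const vec lam0 = exp(log_lam0.col(c));
    const mat K = exp(-D2 / two_s2);
    S.col(c) = K.t() * lam0;
  }
  if (!sex_specific) S.col(1) = S.col(0);

  const vec mu_a = exp(log_mu_a);
  double Lambda_bar = 0.0;
  for (uword c = 0; c < 2; ++c) {
    Lambda_bar += std::exp(log_psi(c)) * dot(mu_a, 1.0 - exp(-S.col(c)));
  }

  double ll = 0.0;
  for (uword i = 0; i < n; ++i) {
    const uword c = static_cast<uword>(sex(i));
    const double two_s2 = 2.0 * sigma(c) * sigma(c);
    vec v = log_mu_a + Ylogl0(i, c) - YD2.row(i).t() / two_s2 - S.col(c);
    const double m = v.max();
    double lse;
    if (!std::isfinite(m)) {
      lse = m;  // data impossible under these parameters
    } else {
      lse = m + std::log(accu(exp(v - m)));
    }
    ll += log_psi(c) + lse - logyfact(i);
  }
  return ll - Lambda_bar;
}

// Posterior activity-centre distributions used for realized-density surfaces.
// Returns G x (n + 1): columns 1..n are per-individual AC posteriors (each sums
// to one); the last column is the expected undetected-individual surface
// sum_c psi_c * mu(g) * a * exp(-S(g, c)).
// [[Rcpp::export]]
arma::mat scr_session_posterior_core(const arma::mat& D2, const arma::vec& log_mu_a,
                                     const arma::mat& log_lam0, const arma::vec& sigma,
                                     const arma::vec& log_psi, const arma::mat& YD2,
                                     const arma::ivec& sex, const bool sex_specific) {
  const uword G = D2.n_cols;
  const uword n = YD2.n_rows;
  const uword n_sex_eval = sex_specific ? 2 : 1;

  mat S(G, 2);
  for (uword c = 0; c < n_sex_eval; ++c) {
    const double two_s2 = 2.0 * sigma(c) * sigma(c);
    const vec lam0 = exp(log_lam0.col(c));
    const mat K = exp(-D2 / two_s2);
    S.col(c) = K.t() * lam0;
  }
  if (!sex_specific) S.col(1) = S.col(0);

  mat out(G, n + 1);
  for (uword i = 0; i < n; ++i) {
    const uword c = static_cast<uword>(sex(i));
    const double two_s2 = 2.0 * sigma(c) * sigma(c);
    vec v = log_mu_a - YD2.row(i).t() / two_s2 - S.col(c);
    const double m = v.max();
    vec w = exp(v - m);
    out.col(i) = w / accu(w);
  }
  vec undet(G, fill::zeros);
  const vec mu_a = exp(log_mu_a);
  for (uword c = 0; c < 2; ++c) {
    undet += std::exp(log_psi(c)) * (mu_a % exp(-S.col(c)));
  }
  out.col(n) = undet;
  return out;
}
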