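// Compiled likelihood core: 3-state intensity matrices, matrix-exponential
// interval probabilities (piecewise-constant covariates within an interval),
// per-participant log-likelihood, and the participant-latent MH sweep used
// by the sampler.  Transition order: (1>2, 1>3, 2>1, 2>3, 3>1, 3>2).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

typedef arma::vec::fixed<6> vec6;
typedef arma::mat::fixed<3, 3> mat33;

static mat33 q_from_rates(const vec6& r) {
  mat33 Q;
  Q(0, 1) = r(0); Q(0, 2) = r(1);
  Q(1, 0) = r(2); Q(1, 2) = r(3);
  Q(2, 0) = r(4); Q(2, 1) = r(5);
  Q(0, 0) = -(r(0) + r(1));
  Q(1, 1) = -(r(2) + r(3));
  Q(2, 2) = -(r(4) + r(5));
  return Q;
}

// [[Rcpp::export]]
arma::mat expm_ctmc_cpp(const arma::mat& Q, double dt) {
  arma::mat P = arma::expmat(Q * dt);
  return P;
}

// log-likelihood of one participant's intervals given its 6 log intensities
// at the reference covariates (mu row) and the directed coefficients.
static double ll_one(int p, // 0-based
                     const arma::rowvec& mu_row,
                     const arma::mat& beta_dir,     // 6 x C
                     const arma::mat& seg_X,        // S x C
                     const arma::vec& seg_dt,
                     const IntegerVector& int_from,
                     const IntegerVector& int_to,
                     const IntegerVector& int_seg_start,
                     const IntegerVector& int_seg_end,
                     const IntegerVector& p_int_start,
                     const IntegerVector& p_int_end,
                     double floor_p, int& n_floored) {
  double ll = 0.0;
  const bool has_cov = beta_dir.n_cols > 0;
  for (int k = p_int_start[p] - 1; k <= p_int_end[p] - 1; ++k) {
    mat33 P(arma::fill::eye);
    for (int s = int_seg_start[k] - 1; s <= int_seg_end[k] - 1; ++s) {
      vec6 eta = mu_row.t();
      if (has_cov) eta += beta_dir * seg_X.row(s).t();
      mat33 Q = q_from_rates(arma::exp(eta));
      P = P * arma::expmat(Q * seg_dt(s));
    }
    double pr = P(int_from[k] - 1, int_to[k] - 1);
    if (pr < floor_p) { pr = floor_p; ++n_floored; }
    ll += std::log(pr);
  }
  return ll;
}

// [[Rcpp::export]]
List loglik_by_participant_cpp(const arma::mat& mu_p,   // n_p x 6
                               const arma::mat& beta_dir,
                               const arma::mat& seg_X,
                               const arma::vec& seg_dt,
                               IntegerVector int_from, IntegerVector int_to,
                               IntegerVector int_seg_start, IntegerVector int_seg_end,
                               IntegerVector p_int_start, IntegerVector p_int_end,
                               double floor_p) {
  const int n_p = p_int_start.size();
  arma::vec ll(n_p, arma::fill::zeros);
  int n_floored = 0;
  for (int p = 0; p < n_p; ++p) {
    ll(p) = ll_one(p, mu_p.row(p), beta_dir, seg_X, seg_dt, int_from, int_to,
                   int_seg_start, int_seg_end, p_int_start, p_int_end,
                   floor_p, n_floored);
  }
  return List::create(_["ll"] = ll, _["n_floored"] = n_floored);
}

// One random-walk Metropolis sweep over the participant latents z_p.
// Uses R's RNG so runs are reproducible under set.seed().
// [[Rcpp::export]]
List update_z_cpp(arma::mat z,                    // n_p x 6 (copied)
                  const arma::vec& mu_hat, const arma::vec& sd_s,
                  const arma::mat& L_s, double mu_sd, double mu_bar,
                  const arma::mat& beta_dir,
                  const arma::mat& seg_X, const arma::vec& seg_dt,
                  IntegerVector int_from, IntegerVector int_to,
                  IntegerVector int_seg_start, IntegerVector int_seg_end,
                  IntegerVector p_int_start, IntegerVector p_int_end,
                  arma::vec ll_cur, double step, double floor_p) {
  const int n_p = z.n_rows;
  int n_accept = 0, n_floored = 0;
  for (int p = 0; p < n_p; ++p) {
    vec6 zp = z.row(p).t();
    vec6 prop;
    for (int j = 0; j < 6; ++j) prop(j) = zp(j) + step * norm_rand();
    vec6 s_new = sd_s % (L_s * prop);
    arma::rowvec mu_new = ((mu_hat + s_new) * mu_sd + mu_bar).t();
    double ll_new = ll_one(p, mu_new, beta_dir, seg_X, seg_dt, int_from, int_to,
                           int_seg_start, int_seg_end, p_int_start, p_int_end,
                           floor_p, n_floored);
    double logr = ll_new - ll_cur(p) +
      0.5 * (arma::dot(zp, zp) - arma::dot(prop, prop));
    if (std::log(unif_rand()) < logr) {
      z.row(p) = prop.t();
      ll_cur(p) = ll_new;
      ++n_accept;
    }
  }
  return List::create(_["z"] = z, _["ll"] = ll_cur,
                      _["n_accept"] = n_accept, _["n_floored"] = n_floored);
}
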