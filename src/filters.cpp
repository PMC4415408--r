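// Compiled filter recursions. Each runner consumes a whole trajectory and
// returns per-step prior and posterior sufficient statistics; the single-step
// algebra is mirrored by the pure-R step functions in R/steps.R.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace Rcpp;

// Joint Gaussian belief filter over (z, w).
// mode 0: full joint filter (cross-covariance propagated).
// mode 1: RLS-as-modified-joint-filter: the prediction drops the incoming
//         cross-covariance (independence assumption on differenced
//         observations) and the update uses the inflated variance 2*sigma_s^2.
// [[Rcpp::export]]
List run_joint_filter_cpp(const arma::vec& x, const arma::mat& Q,
                          double sigma_p, double sigma_s,
                          double mu_z0, const arma::vec& mu_w0,
                          double Szz0, const arma::mat& Sww0,
                          const arma::rowvec& Szw0,
                          int mode, double jitter) {
  const int N = x.n_elem;
  const int Dq = Q.n_cols;
  if ((int)mu_w0.n_elem != Dq || (int)Sww0.n_rows != Dq || (int)Szw0.n_elem != Dq)
    stop("dimension mismatch between commands and weight belief");
  if ((int)Q.n_rows != N)
    stop("commands and measurements must have equal length");

  double mz = mu_z0, Szz = Szz0;
  arma::vec mw = mu_w0;
  arma::mat Sww = Sww0;
  arma::rowvec Szw = Szw0;

  const double sp2 = sigma_p * sigma_p;
  const double s2_obs = (mode == 1) ? 2.0 * sigma_s * sigma_s
                                    : sigma_s * sigma_s;

  arma::vec mu_z_prior(N), mu_z_post(N), Szz_prior(N), Szz_post(N);
  arma::mat MW(N, Dq), SWWd(N, Dq), SZW(N, Dq);

  for (int n = 0; n < N; ++n) {
    arma::vec q = Q.row(n).t();
    arma::vec Swwq = Sww * q;
    double quad = arma::dot(q, Swwq);

    // prediction
    double mzp = mz + arma::dot(q, mw);
    double Szzp;
    arma::rowvec Szwp;
    if (mode == 1) {
      Szzp = Szz + sp2 + quad;
      Szwp = Swwq.t();
    } else {
      Szzp = Szz + sp2 + quad + 2.0 * arma::dot(Szw, q);
      Szwp = Szw + Swwq.t();
    }

    // measurement update
    double denom = s2_obs + Szzp;
    if (denom <= 0.0)
      stop("degenerate update: sigma_s^2 + Sigma_zz is zero at step %d", n + 1);
    double resid = x(n) - mzp;
    mz = mzp + (Szzp / denom) * resid;
    Szz = s2_obs * Szzp / denom;
    mw += Szwp.t() * (resid / denom);
    Sww -= (Szwp.t() * Szwp) / denom;
    Sww = 0.5 * (Sww + Sww.t());
    Szw = (s2_obs / denom) * Szwp;
    if (jitter > 0.0) {
      Sww.diag() += jitter;
      Szz += jitter;
    }

    mu_z_prior(n) = mzp; mu_z_post(n) = mz;
    Szz_prior(n) = Szzp; Szz_post(n) = Szz;
    MW.row(n) = mw.t();
    SWWd.row(n) = Sww.diag().t();
    SZW.row(n) = Szw;
  }

  return List::create(
    _["mu_z_prior"] = mu_z_prior, _["mu_z_post"] = mu_z_post,
    _["Sigma_zz_prior"] = Szz_prior, _["Sigma_zz_post"] = Szz_post,
    _["mu_w"] = MW, _["Sigma_ww_diag"] = SWWd, _["Sigma_zw"] = SZW,
    _["Sigma_ww_final"] = Sww, _["Sigma_zw_final"] = Szw);
}

// Kalman filter with known weights w.
// [[Rcpp::export]]
List run_kalman_cpp(const arma::vec& x, const arma::mat& Q,
                    const arma::vec& w, double sigma_p, double sigma_s,
                    double mu_z0, double Szz0) {
  const int N = x.n_elem;
  if (Q.n_cols != w.n_elem) stop("dimension mismatch between commands and w");
  if ((int)Q.n_rows != N) stop("commands and measurements must have equal length");

  double mz = mu_z0, Szz = Szz0;
  const double sp2 = sigma_p * sigma_p, ss2 = sigma_s * sigma_s;
  arma::vec mu_z_prior(N), mu_z_post(N), Szz_prior(N), Szz_post(N);

  for (int n = 0; n < N; ++n) {
    double mzp = mz + arma::dot(Q.row(n).t(), w);
    double Szzp = Szz + sp2;
    double denom = ss2 + Szzp;
    if (denom <= 0.0)
      stop("degenerate update: sigma_s^2 + Sigma_zz is zero at step %d", n + 1);
    mz = mzp + (Szzp / denom) * (x(n) - mzp);
    Szz = ss2 * Szzp / denom;
    mu_z_prior(n) = mzp; mu_z_post(n) = mz;
    Szz_prior(n) = Szzp; Szz_post(n) = Szz;
  }
  return List::create(
    _["mu_z_prior"] = mu_z_prior, _["mu_z_post"] = mu_z_post,
    _["Sigma_zz_prior"] = Szz_prior, _["Sigma_zz_post"] = Szz_post);
}

// Two-block architectures coupling a classical RLS weight learner with a
// known-weight-style Kalman filter.
//
// loop = false ("RLS -> Kalman"): RLS regresses commands on differences of
//   consecutive raw measurements x_n - x_{n-1} (available from the second
//   measurement on); within a step RLS ingests its pair first, then the
//   Kalman filter predicts with the updated weight estimate, inflating its
//   prediction variance by q' Vw q where Vw is the OLS standard-error
//   covariance s^2 (ridge I + sum qq')^{-1}; until the estimate has a degree
//   of freedom the RLS prior covariance Sww0 is injected instead.
//
// loop = true ("Kalman <-> RLS"): the Kalman filter runs first using the
//   weight estimate from the previous step, then RLS consumes differences of
//   consecutive Kalman posterior means (from the second measurement on).
//   The feedback closes the self-delusional loop.
// [[Rcpp::export]]
List run_rls_kalman_cpp(const arma::vec& x, const arma::mat& Q,
                        double sigma_p, double sigma_s,
                        double mu_z0, double Szz0,
                        const arma::vec& mu_w0, const arma::mat& Sww0,
                        bool loop, double ridge) {
  const int N = x.n_elem;
  const int Dq = Q.n_cols;
  if ((int)mu_w0.n_elem != Dq || (int)Sww0.n_rows != Dq)
    stop("dimension mismatch between commands and weight prior");
  if ((int)Q.n_rows != N) stop("commands and measurements must have equal length");

  const double sp2 = sigma_p * sigma_p, ss2 = sigma_s * sigma_s;

  arma::mat A = ridge * arma::eye(Dq, Dq);
  arma::vec b(Dq, arma::fill::zeros);
  arma::vec mw = mu_w0;
  int n_obs = 0;
  double rss = 0.0;

  double mz = mu_z0, Szz = Szz0;
  double prev_post = mu_z0;   // mu_z,0|0 (used only to track the lag)
  bool have_prev_post = false;

  arma::vec mu_z_prior(N), mu_z_post(N), Szz_prior(N), Szz_post(N);
  arma::mat MW(N, Dq), VWd(N, Dq);

  auto rls_ingest = [&](const arma::vec& q, double y) {
    double e = y - arma::dot(q, mw);
    A += q * q.t();
    b += q * y;
    mw = arma::solve(A, b, arma::solve_opts::likely_sympd);
    double ehat = y - arma::dot(q, mw);
    rss += e * ehat;
    if (rss < 0.0) rss = 0.0;
    ++n_obs;
  };
  auto rls_variance = [&]() -> arma::mat {
    if (n_obs <= Dq) return Sww0;
    double s2 = rss / std::max(n_obs - Dq, 1);
    return s2 * arma::inv_sympd(A);
  };

  for (int n = 0; n < N; ++n) {
    arma::vec q = Q.row(n).t();

    if (!loop && n >= 1) rls_ingest(q, x(n) - x(n - 1));

    arma::mat Vw = rls_variance();
    double mzp = mz + arma::dot(q, mw);
    double Szzp = Szz + sp2 + arma::as_scalar(q.t() * Vw * q);
    double denom = ss2 + Szzp;
    if (denom <= 0.0)
      stop("degenerate update: sigma_s^2 + Sigma_zz is zero at step %d", n + 1);
    double mz_new = mzp + (Szzp / denom) * (x(n) - mzp);
    double Szz_new = ss2 * Szzp / denom;

    if (loop) {
      if (have_prev_post) rls_ingest(q, mz_new - prev_post);
      prev_post = mz_new;
      have_prev_post = true;
    }

    mz = mz_new; Szz = Szz_new;
    mu_z_prior(n) = mzp; mu_z_post(n) = mz;
    Szz_prior(n) = Szzp; Szz_post(n) = Szz;
    MW.row(n) = mw.t();
    VWd.row(n) = rls_variance().diag().t();
  }

  return List::create(
    _["mu_z_prior"] = mu_z_prior, _["mu_z_post"] = mu_z_post,
    _["Sigma_zz_prior"] = Szz_prior, _["Sigma_zz_post"] = Szz_post,
    _["mu_w"] = MW, _["var_w_diag"] = VWd,
    _["n_obs"] = n_obs, _["rss"] = rss);
}
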