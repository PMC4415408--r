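#' Fit a filtering architecture to a trajectory
#'
#' Runs one of five online estimators over a simulated (or user-supplied)
#' trajectory of commands and measurements, returning the full sequence of
#' prior (`n|n-1`) and posterior (`n|n`) sufficient statistics. Priors are
#' retained because residual-based metrics need the one-step-ahead
#' prediction.
#'
#' Methods:
#' \describe{
#'   \item{`"piaf"`}{the joint Gaussian filter over `(z, w)` with full
#'     cross-covariance bookkeeping (Bayes-optimal; equivalent to an
#'     augmented-state joint Kalman filter).}
#'   \item{`"kalman"`}{the classical Kalman filter handed the true weights
#'     `w`.}
#'   \item{`"rls_piaf"`}{recursive least squares written as a modified joint
#'     filter: cross-covariance dropped in prediction, sensor variance
#'     inflated to \eqn{2\sigma_s^2} (see [rls_piaf_step()]).}
#'   \item{`"rls_kalman"`}{decoupled coupling: classical RLS learns `w` from
#'     differences of raw measurements and feeds its estimate and
#'     standard-error variance to a Kalman filter.}
#'   \item{`"kalman_rls"`}{feedback coupling: RLS learns from differences of
#'     consecutive Kalman posterior means; prone to the self-delusional
#'     loop.}
#' }
#'
#' @param trajectory a [piaf_trajectory()] (or a list with numeric `x` and a
#'   command matrix `qdot`; the latent `z`, when present, enables
#'   error-reporting methods).
#' @param method which estimator to run.
#' @param priors a [joint_belief()]; defaults to [piaf_priors()]. For
#'   `"kalman"` only `mu_z` and `Sigma_zz` are used; for the RLS couplings
#'   `mu_w` and `Sigma_ww` seed the learner.
#' @param w true weights for `method = "kalman"`; defaults to the simulating
#'   system's weights when the trajectory carries them.
#' @param sigma_s,sigma_p noise standard deviations assumed by the filter;
#'   default to the simulating system's values.
#' @param jitter nonnegative variance floor added per step to `Sigma_zz` and
#'   `diag(Sigma_ww)` (default 0; exposed for long-horizon robustness
#'   experiments).
#' @param ridge ridge seed of the RLS information matrix (couplings only).
#' @return An object of class `piaf_fit` with per-step vectors/matrices
#'   `mu_z_prior`, `mu_z_post`, `Sigma_zz_prior`, `Sigma_zz_post`, `mu_w`
#'   (`N x D_q`), `var_w_diag`, and (joint methods) `Sigma_zw`, plus the
#'   final weight covariance. Supports `print`, `summary`, `coef`, `fitted`,
#'   `residuals`, `predict`, `plot`, `logLik` and `as.data.frame`.
#' @examples
#' sys <- piaf_system(w = 1, sigma_s = 2, sigma_p = 0)
#' set.seed(3)
#' tr <- simulate_trajectory(sys, control_sinusoidal(500), z0 = 0)
#' fit <- piaf(tr)
#' coef(fit)
#' summary(fit)
#' @export
piaf <- function(trajectory,
                 method = c("piaf", "kalman", "rls_piaf", "rls_kalman",
                            "kalman_rls"),
                 priors = NULL, w = NULL, sigma_s = NULL, sigma_p = NULL,
                 jitter = 0, ridge = 1e-8) {
  method <- match.arg(method)
  x <- as.numeric(trajectory$x)
  Q <- as.matrix(trajectory$qdot)
  N <- length(x)
  if (N < 1L) stop("trajectory contains no measurements")
  if (nrow(Q) != N) stop("lengths of 'x' and 'qdot' differ")
  Dq <- ncol(Q)
  sys <- trajectory$system
  if (is.null(sigma_s)) sigma_s <- sys$sigma_s
  if (is.null(sigma_p)) sigma_p <- sys$sigma_p
  if (is.null(sigma_s) || is.null(sigma_p))
    stop("'sigma_s' and 'sigma_p' must be given when the trajectory carries no system")
  if (is.null(priors)) priors <- piaf_priors(Dq)
  validate_belief(priors)
  if (priors$D_q != Dq) stop("priors have D_q = ", priors$D_q,
                             " but commands have dimension ", Dq)

  res <- switch(method,
    piaf = ,
    rls_piaf = {
      out <- run_joint_filter_cpp(x, Q, sigma_p, sigma_s,
                                  priors$mu_z, priors$mu_w, priors$Sigma_zz,
                                  priors$Sigma_ww, matrix(priors$Sigma_zw, 1),
                                  mode = if (method == "rls_piaf") 1L else 0L,
                                  jitter = jitter)
      list(mu_z_prior = out$mu_z_prior, mu_z_post = out$mu_z_post,
           Sigma_zz_prior = out$Sigma_zz_prior,
           Sigma_zz_post = out$Sigma_zz_post,
           mu_w = out$mu_w, var_w_diag = out$Sigma_ww_diag,
           Sigma_zw = out$Sigma_zw,
           Sigma_ww_final = out$Sigma_ww_final,
           Sigma_zw_final = as.numeric(out$Sigma_zw_final))
    },
    kalman = {
      if (is.null(w)) w <- sys$w
      if (is.null(w)) stop("method 'kalman' needs the true weights 'w'")
      if (length(w) != Dq) stop("length(w) does not match command dimension")
      out <- run_kalman_cpp(x, Q, as.numeric(w), sigma_p, sigma_s,
                            priors$mu_z, priors$Sigma_zz)
      list(mu_z_prior = out$mu_z_prior, mu_z_post = out$mu_z_post,
           Sigma_zz_prior = out$Sigma_zz_prior,
           Sigma_zz_post = out$Sigma_zz_post,
           mu_w = matrix(w, N, Dq, byrow = TRUE),
           var_w_diag = matrix(0, N, Dq),
           Sigma_ww_final = matrix(0, Dq, Dq),
           Sigma_zw_final = rep(0, Dq))
    },
    rls_kalman = ,
    kalman_rls = {
      out <- run_rls_kalman_cpp(x, Q, sigma_p, sigma_s,
                                priors$mu_z, priors$Sigma_zz,
                                priors$mu_w, priors$Sigma_ww,
                                loop = (method == "kalman_rls"), ridge = ridge)
      Vfin <- diag(as.numeric(out$var_w_diag[N, ]), nrow = Dq)
      list(mu_z_prior = out$mu_z_prior, mu_z_post = out$mu_z_post,
           Sigma_zz_prior = out$Sigma_zz_prior,
           Sigma_zz_post = out$Sigma_zz_post,
           mu_w = out$mu_w, var_w_diag = out$var_w_diag,
           Sigma_ww_final = Vfin,
           Sigma_zw_final = rep(0, Dq))
    })

  # the compiled runners return N x 1 matrices for scalar series
  for (f in c("mu_z_prior", "mu_z_post", "Sigma_zz_prior", "Sigma_zz_post"))
    res[[f]] <- as.numeric(res[[f]])

  structure(c(res,
              list(method = method, N = N, D_q = Dq,
                   sigma_s = sigma_s, sigma_p = sigma_p,
                   priors = priors, trajectory = trajectory,
                   call = match.call())),
            class = "piaf_fit")
}
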