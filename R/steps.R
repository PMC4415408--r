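#' Prediction step of the joint filter
#'
#' Propagates the joint belief through one state transition driven by command
#' `qdot`. The state mean moves by \eqn{\dot q^T \mu_w}; the state variance
#' absorbs the process noise, the weight uncertainty mapped through the
#' command, and twice the cross term:
#' \deqn{\Sigma_{zz} \leftarrow \Sigma_{zz} + \sigma_p^2 +
#'       \dot q^T \Sigma_{ww} \dot q + 2 \Sigma_{zw} \dot q,}
#' and the cross-covariance picks up \eqn{\dot q^T \Sigma_{ww}}. Applying a
#' command reveals nothing about the weights, so \eqn{\mu_w} and
#' \eqn{\Sigma_{ww}} are unchanged.
#'
#' @param belief a [joint_belief()] (posterior at `n-1|n-1`).
#' @param qdot command vector (length `D_q`).
#' @param sigma_p process-noise standard deviation.
#' @return The prior belief at `n|n-1`, a [joint_belief()].
#' @seealso [piaf_update()], [piaf_step()]
#' @export
piaf_predict <- function(belief, qdot, sigma_p) {
  validate_belief(belief)
  qdot <- as.numeric(qdot)
  if (length(qdot) != belief$D_q)
    stop("command dimension does not match belief (D_q = ", belief$D_q, ")")
  Swwq <- as.numeric(belief$Sigma_ww %*% qdot)
  joint_belief(
    mu_z = belief$mu_z + sum(qdot * belief$mu_w),
    mu_w = belief$mu_w,
    Sigma_zz = belief$Sigma_zz + sigma_p^2 + sum(qdot * Swwq) +
      2 * sum(belief$Sigma_zw * qdot),
    Sigma_ww = belief$Sigma_ww,
    Sigma_zw = belief$Sigma_zw + Swwq)
}

#' Measurement update of the joint filter
#'
#' Fuses the measurement `x` into the prior belief. With gain
#' \eqn{g = \Sigma_{zz} / (\sigma_s^2 + \Sigma_{zz})} the state mean is
#' corrected by the prediction error \eqn{x - \mu_z}; the same prediction
#' error, routed through the cross-covariance, updates the weight estimate:
#' \deqn{\mu_w \leftarrow \mu_w + \frac{\Sigma_{zw}^T}{\sigma_s^2 +
#'       \Sigma_{zz}} (x - \mu_z), \qquad
#'       \Sigma_{ww} \leftarrow \Sigma_{ww} - \frac{\Sigma_{zw}^T
#'       \Sigma_{zw}}{\sigma_s^2 + \Sigma_{zz}}.}
#' The state variance strictly decreases whenever the prior variance is
#' positive and the sensor noise finite. `Sigma_ww` is re-symmetrized after
#' the rank-one downdate to counter floating-point drift.
#'
#' @param belief the prior [joint_belief()] at `n|n-1`.
#' @param x scalar measurement.
#' @param sigma_s sensor-noise standard deviation.
#' @return The posterior belief at `n|n`, a [joint_belief()].
#' @export
piaf_update <- function(belief, x, sigma_s) {
  validate_belief(belief)
  s2 <- sigma_s^2
  denom <- s2 + belief$Sigma_zz
  if (denom <= 0)
    stop("degenerate update: sigma_s^2 + Sigma_zz is zero; nothing to fuse")
  resid <- x - belief$mu_z
  Sww <- belief$Sigma_ww - tcrossprod(belief$Sigma_zw) / denom
  joint_belief(
    mu_z = belief$mu_z + belief$Sigma_zz / denom * resid,
    mu_w = belief$mu_w + belief$Sigma_zw * resid / denom,
    Sigma_zz = s2 * belief$Sigma_zz / denom,
    Sigma_ww = (Sww + t(Sww)) / 2,
    Sigma_zw = s2 / denom * belief$Sigma_zw)
}

#' One full filter iteration
#'
#' Convenience wrapper: prediction with `qdot` followed by measurement update
#' with `x`.
#'
#' @inheritParams piaf_predict
#' @inheritParams piaf_update
#' @param sigma_s sensor-noise standard deviation.
#' @return List with elements `prior` (belief at `n|n-1`) and `posterior`
#'   (belief at `n|n`).
#' @export
piaf_step <- function(belief, qdot, x, sigma_p, sigma_s) {
  prior <- piaf_predict(belief, qdot, sigma_p)
  list(prior = prior, posterior = piaf_update(prior, x, sigma_s))
}

#' RLS as a modified joint filter: one iteration
#'
#' The recursive-least-squares learner on differenced observations, written
#' in the same joint-belief parameterization as the full filter. Its
#' independence assumption on consecutive differenced observations amounts to
#' two modifications: the prediction discards the incoming cross-covariance
#' (\deqn{\Sigma_{zz} \leftarrow \Sigma_{zz} + \sigma_p^2 + \dot q^T
#' \Sigma_{ww} \dot q, \qquad \Sigma_{zw} \leftarrow \dot q^T \Sigma_{ww},})
#' and the update replaces \eqn{\sigma_s^2} by the inflated variance
#' \eqn{2\sigma_s^2} (each differenced observation carries two copies of the
#' sensor noise).
#'
#' @inheritParams piaf_step
#' @return List with elements `prior` and `posterior` ([joint_belief()]s).
#' @export
rls_piaf_step <- function(belief, qdot, x, sigma_p, sigma_s) {
  prior <- rls_piaf_predict(belief, qdot, sigma_p)
  list(prior = prior, posterior = piaf_update(prior, x, sqrt(2) * sigma_s))
}

#' @rdname rls_piaf_step
#' @export
rls_piaf_predict <- function(belief, qdot, sigma_p) {
  validate_belief(belief)
  qdot <- as.numeric(qdot)
  if (length(qdot) != belief$D_q)
    stop("command dimension does not match belief (D_q = ", belief$D_q, ")")
  Swwq <- as.numeric(belief$Sigma_ww %*% qdot)
  joint_belief(
    mu_z = belief$mu_z + sum(qdot * belief$mu_w),
    mu_w = belief$mu_w,
    Sigma_zz = belief$Sigma_zz + sigma_p^2 + sum(qdot * Swwq),
    Sigma_ww = belief$Sigma_ww,
    Sigma_zw = Swwq)
}

#' Known-weights Kalman filter: one iteration
#'
#' The classical filter that is handed the true weights: prediction
#' \eqn{\mu_z \leftarrow \mu_z + \dot q^T w},
#' \eqn{\Sigma_{zz} \leftarrow \Sigma_{zz} + \sigma_p^2}, followed by the
#' same measurement update as the joint filter's state block.
#'
#' @param belief list with fields `mu_z`, `Sigma_zz` (see [kalman_belief()]).
#' @param qdot command vector.
#' @param x scalar measurement.
#' @param w true weight vector.
#' @param sigma_p,sigma_s noise standard deviations.
#' @return List with `prior` and `posterior` `kalman_belief` objects.
#' @export
kalman_step <- function(belief, qdot, x, w, sigma_p, sigma_s) {
  stopifnot(inherits(belief, "kalman_belief"))
  if (length(qdot) != length(w)) stop("command dimension does not match w")
  mzp <- belief$mu_z + sum(as.numeric(qdot) * w)
  Szzp <- belief$Sigma_zz + sigma_p^2
  denom <- sigma_s^2 + Szzp
  if (denom <= 0)
    stop("degenerate update: sigma_s^2 + Sigma_zz is zero; nothing to fuse")
  prior <- kalman_belief(mzp, Szzp)
  post <- kalman_belief(mzp + Szzp / denom * (x - mzp),
                        sigma_s^2 * Szzp / denom)
  list(prior = prior, posterior = post)
}

#' State-only Kalman belief
#'
#' @param mu_z state mean.
#' @param Sigma_zz state variance, `>= 0`.
#' @return Object of class `kalman_belief`.
#' @export
kalman_belief <- function(mu_z = 0, Sigma_zz = 1e4) {
  if (Sigma_zz < 0) stop("Sigma_zz must be nonnegative")
  structure(list(mu_z = as.numeric(mu_z), Sigma_zz = as.numeric(Sigma_zz)),
            class = "kalman_belief")
}

#' Augmented-state joint Kalman filter: one iteration
#'
#' Textbook Kalman filter on the augmented state \eqn{(z, w)} with transition
#' \eqn{F = [[1, \dot q^T], [0, I]]}, process covariance
#' \eqn{Q = diag(\sigma_p^2, 0, \ldots, 0)} (the weights have no dynamics),
#' observation row \eqn{H = [1, 0, \ldots, 0]} and measurement noise
#' \eqn{\sigma_s^2}. Algebraically equivalent to [piaf_step()]; kept as an
#' independently coded reference path.
#'
#' @param mean augmented mean vector, length `1 + D_q` (state first).
#' @param cov augmented covariance, `(1 + D_q) x (1 + D_q)`.
#' @param qdot command vector.
#' @param x scalar measurement.
#' @param sigma_p,sigma_s noise standard deviations.
#' @return List with `mean`, `cov` (posterior) and `pred_mean`, `pred_cov`
#'   (prior).
#' @export
joint_kalman_step <- function(mean, cov, qdot, x, sigma_p, sigma_s) {
  Dq <- length(mean) - 1L
  qdot <- as.numeric(qdot)
  stopifnot(length(qdot) == Dq, all(dim(as.matrix(cov)) == length(mean)))
  F <- rbind(c(1, qdot), cbind(rep(0, Dq), diag(Dq)))
  Qm <- diag(c(sigma_p^2, rep(0, Dq)), nrow = Dq + 1L)
  H <- matrix(c(1, rep(0, Dq)), nrow = 1L)
  pm <- as.numeric(F %*% mean)
  Pp <- F %*% cov %*% t(F) + Qm
  Pp <- (Pp + t(Pp)) / 2
  S <- as.numeric(H %*% Pp %*% t(H)) + sigma_s^2
  if (S <= 0) stop("innovation variance is zero; degenerate update")
  K <- (Pp %*% t(H)) / S
  m <- pm + as.numeric(K) * (x - pm[1L])
  P <- (diag(Dq + 1L) - K %*% H) %*% Pp
  P <- (P + t(P)) / 2
  list(mean = m, cov = P, pred_mean = pm, pred_cov = Pp)
}

#' Classical recursive least squares on differenced observations
#'
#' Standard information-matrix RLS for the regression
#' \eqn{\dot x_n = \dot q_n^T w + noise}, with a rank-one accumulator
#' \eqn{A \leftarrow A + \dot q \dot q^T}, \eqn{b \leftarrow b + \dot q
#' \dot x}, and the exact recursive residual-sum-of-squares update
#' \eqn{rss \leftarrow rss + e \hat e} (prior times posterior residual). A
#' ridge term `ridge * I` seeds the information matrix so the
#' pre-identifiability phase never crashes.
#'
#' @param state an [rls_state()].
#' @param qdot regressor (command) vector.
#' @param xdot differenced observation \eqn{x_n - x_{n-1}}.
#' @return The updated `rls_state`.
#' @seealso [rls_variance()] for the standard-error-based covariance.
#' @export
rls_step <- function(state, qdot, xdot) {
  stopifnot(inherits(state, "rls_state"))
  q <- as.numeric(qdot)
  if (length(q) != state$D_q) stop("regressor dimension does not match state")
  e <- xdot - sum(q * state$mu_w)
  state$A <- state$A + tcrossprod(q)
  state$b <- state$b + q * xdot
  state$mu_w <- as.numeric(solve(state$A, state$b))
  ehat <- xdot - sum(q * state$mu_w)
  state$rss <- max(state$rss + e * ehat, 0)
  state$n_obs <- state$n_obs + 1L
  state
}

#' @param D_q regressor dimension.
#' @param ridge nonnegative ridge seed for the information matrix.
#' @rdname rls_step
#' @export
rls_state <- function(D_q = 1, ridge = 1e-8) {
  structure(list(A = ridge * diag(D_q), b = rep(0, D_q),
                 mu_w = rep(0, D_q), n_obs = 0L, rss = 0,
                 D_q = as.integer(D_q), ridge = ridge),
            class = "rls_state")
}

#' Standard-error covariance of an RLS estimate
#'
#' The ordinary-least-squares standard-error covariance
#' \eqn{s^2 A^{-1}} with \eqn{s^2 = rss / \max(n_{obs} - D_q, 1)}. Before
#' `D_q` observations have been absorbed the estimate is not identified and a
#' matrix of `Inf` is returned as an explicit "undefined/large" sentinel.
#'
#' @param state an [rls_state()].
#' @return A `D_q x D_q` covariance matrix (possibly the `Inf` sentinel).
#' @export
rls_variance <- function(state) {
  stopifnot(inherits(state, "rls_state"))
  if (state$n_obs < state$D_q)
    return(matrix(Inf, state$D_q, state$D_q))
  s2 <- state$rss / max(state$n_obs - state$D_q, 1L)
  s2 * solve(state$A)
}
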