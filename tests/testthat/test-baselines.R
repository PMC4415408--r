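test_that("recursive least squares matches the batch solution at every step", {
  set.seed(201)
  Dq <- 2
  st <- rls_state(Dq, ridge = 1e-8)
  Q <- matrix(rnorm(50 * Dq), 50, Dq)
  y <- as.numeric(Q %*% c(1.5, -0.7)) + rnorm(50, sd = 0.3)
  for (n in 1:50) {
    st <- rls_step(st, Q[n, ], y[n])
    if (n >= Dq) {
      Qn <- Q[1:n, , drop = FALSE]
      batch <- solve(1e-8 * diag(Dq) + crossprod(Qn), crossprod(Qn, y[1:n]))
      expect_equal(st$mu_w, as.numeric(batch), tolerance = 1e-10)
      # recursive residual sum of squares equals the direct one
      expect_equal(st$rss, sum((y[1:n] - Qn %*% st$mu_w)^2), tolerance = 1e-6)
    }
  }
  # final estimate agrees with lm() up to the vanishing ridge
  fit_lm <- lm(y ~ Q - 1)
  expect_equal(st$mu_w, unname(coef(fit_lm)), tolerance = 1e-5)
  # and the standard-error covariance matches lm's
  expect_equal(rls_variance(st), unname(vcov(fit_lm)), tolerance = 1e-4)
})

test_that("noiseless repeated pairs give an exact fit with zero residual", {
  st <- rls_state(1, ridge = 0)   # no ridge so the fit is exact
  for (n in 1:5) st <- rls_step(st, 1, 1)
  expect_equal(st$mu_w, 1, tolerance = 1e-7)
  expect_lt(st$rss, 1e-12)
})

test_that("pre-identifiability variance is the explicit sentinel", {
  st <- rls_state(2)
  expect_true(all(rls_variance(st) == Inf))
  st <- rls_step(st, c(1, 0), 1)
  expect_true(all(rls_variance(st) == Inf))   # 1 obs < D_q = 2
  st <- rls_step(st, c(0, 1), -1)
  expect_true(all(is.finite(rls_variance(st))))
})

test_that("joint Kalman reference: zero weight block freezes the weights and matches the state filter", {
  set.seed(202)
  w <- c(0.5, 0.2)
  m <- c(1, w)
  P <- diag(c(2, 0, 0))
  kb <- kalman_belief(1, 2)
  for (n in 1:30) {
    q <- rnorm(2, sd = 0.3)
    x <- rnorm(1)
    jk <- joint_kalman_step(m, P, q, x, sigma_p = 0.1, sigma_s = 1)
    ks <- kalman_step(kb, q, x, w, sigma_p = 0.1, sigma_s = 1)
    expect_equal(jk$mean[-1], w, tolerance = 1e-12)     # static parameters
    expect_equal(jk$mean[1], ks$posterior$mu_z, tolerance = 1e-12)
    expect_equal(jk$cov[1, 1], ks$posterior$Sigma_zz, tolerance = 1e-12)
    m <- jk$mean
    P <- jk$cov
    kb <- ks$posterior
  }
})

test_that("noiseless couplings recover the weights and track exactly", {
  set.seed(203)
  sys <- piaf_system(w = 0.8, sigma_s = 0, sigma_p = 0)
  tr <- simulate_trajectory(sys, control_sinusoidal(100, phi = 0.4),
                            z0 = sin(0.4))
  for (method in c("rls_kalman", "kalman_rls")) {
    fit <- piaf(tr, method)
    # from the second step on the learner has one exact pair
    expect_equal(as.numeric(fit$mu_w[3:100, 1]), rep(0.8, 98),
                 tolerance = 1e-5)   # up to the 1e-8 ridge seed
    # sigma_s = 0 makes the filter gain 1: posterior equals the true state
    expect_equal(fit$mu_z_post, tr$z[-1], tolerance = 1e-8)
  }
})

test_that("decoupled coupling matches a hand-rolled 3-step trace", {
  sys <- piaf_system(w = 0.8, sigma_s = 0.5, sigma_p = 0.2)
  x <- c(1.0, 0.3, -0.4)
  Q <- matrix(c(0.5, -0.2, 0.9), 3, 1)
  tr <- list(x = x, qdot = Q, system = sys)
  fit <- piaf(tr, "rls_kalman")

  pri <- piaf_priors(1)
  st <- rls_state(1, ridge = 1e-8)
  mu <- pri$mu_z
  S <- pri$Sigma_zz
  for (n in 1:3) {
    if (n >= 2) st <- rls_step(st, Q[n, ], x[n] - x[n - 1])
    Vw <- if (st$n_obs > 1) rls_variance(st)[1, 1] else pri$Sigma_ww[1, 1]
    mzp <- mu + Q[n, 1] * st$mu_w
    Szzp <- S + 0.2^2 + Q[n, 1]^2 * Vw
    denom <- 0.5^2 + Szzp
    mu <- mzp + Szzp / denom * (x[n] - mzp)
    S <- 0.5^2 * Szzp / denom
    expect_equal(fit$mu_z_prior[n], mzp, tolerance = 1e-12)
    expect_equal(fit$mu_z_post[n], mu, tolerance = 1e-12)
    expect_equal(fit$Sigma_zz_post[n], S, tolerance = 1e-12)
    expect_equal(fit$mu_w[n, 1], st$mu_w, tolerance = 1e-12)
  }
})

test_that("feedback coupling matches a hand-rolled 3-step trace", {
  sys <- piaf_system(w = 0.8, sigma_s = 0.5, sigma_p = 0.2)
  x <- c(1.0, 0.3, -0.4)
  Q <- matrix(c(0.5, -0.2, 0.9), 3, 1)
  tr <- list(x = x, qdot = Q, system = sys)
  fit <- piaf(tr, "kalman_rls")

  pri <- piaf_priors(1)
  st <- rls_state(1, ridge = 1e-8)
  mu <- pri$mu_z
  S <- pri$Sigma_zz
  prev_post <- NULL
  for (n in 1:3) {
    Vw <- if (st$n_obs > 1) rls_variance(st)[1, 1] else pri$Sigma_ww[1, 1]
    mzp <- mu + Q[n, 1] * st$mu_w
    Szzp <- S + 0.2^2 + Q[n, 1]^2 * Vw
    denom <- 0.5^2 + Szzp
    mu_new <- mzp + Szzp / denom * (x[n] - mzp)
    S <- 0.5^2 * Szzp / denom
    if (!is.null(prev_post)) st <- rls_step(st, Q[n, ], mu_new - prev_post)
    prev_post <- mu_new
    mu <- mu_new
    expect_equal(fit$mu_z_prior[n], mzp, tolerance = 1e-12)
    expect_equal(fit$mu_z_post[n], mu, tolerance = 1e-12)
    expect_equal(fit$mu_w[n, 1], st$mu_w, tolerance = 1e-12)
  }
})

test_that("the independence-assuming filter variant never outperforms the joint filter", {
  cfg_piaf <- experiment_config(method = "piaf", regime = "gaussian",
                                sigma_p = 0.1, N = 500, n_runs = 300,
                                seed = 17)
  cfg_rls <- experiment_config(method = "rls_piaf", regime = "gaussian",
                               sigma_p = 0.1, N = 500, n_runs = 300,
                               seed = 17)
  cv_piaf <- mse_curves(cfg_piaf)
  cv_rls <- mse_curves(cfg_rls)
  idx <- 10:500
  # never better than the optimal filter, up to Monte-Carlo noise
  expect_true(all(cv_rls$mse_w[idx] >= 0.9 * cv_piaf$mse_w[idx]))
  expect_gt(mean(cv_rls$mse_w[idx] > cv_piaf$mse_w[idx]), 0.9)
})
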