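test_that("prediction matches the brute-force affine-map oracle", {
  set.seed(101)
  for (Dq in 1:3) {
    for (rep in 1:20) {
      b <- random_belief(Dq)
      q <- rnorm(Dq)
      sp <- runif(1, 0, 0.5)
      pr <- piaf_predict(b, q, sp)
      or <- oracle_predict(belief_mean(b), joint_covariance(b), q, sp)
      expect_belief_close(pr, or$mean, or$cov, tol = 1e-11)
    }
  }
})

test_that("measurement update matches brute-force Gaussian conditioning", {
  set.seed(102)
  for (Dq in 1:3) {
    for (rep in 1:20) {
      b <- random_belief(Dq)
      x <- rnorm(1, b$mu_z, 2)
      ss <- runif(1, 0.2, 3)
      po <- piaf_update(b, x, ss)
      or <- oracle_condition(belief_mean(b), joint_covariance(b), x, ss)
      expect_belief_close(po, or$mean, or$cov, tol = 1e-10)
    }
  }
})

test_that("full step equals the augmented-state joint Kalman filter over a sequence", {
  set.seed(103)
  for (Dq in c(1L, 3L)) {
    b <- piaf_priors(Dq)
    m <- belief_mean(b)
    P <- joint_covariance(b)
    for (n in 1:200) {
      q <- rnorm(Dq, sd = 0.2)
      x <- rnorm(1, sd = 2)
      st <- piaf_step(b, q, x, sigma_p = 0.05, sigma_s = 1.5)
      jk <- joint_kalman_step(m, P, q, x, sigma_p = 0.05, sigma_s = 1.5)
      expect_equal(belief_mean(st$prior), jk$pred_mean, tolerance = 1e-9)
      expect_equal(joint_covariance(st$prior), jk$pred_cov,
                   tolerance = 1e-9, ignore_attr = TRUE)
      expect_equal(belief_mean(st$posterior), jk$mean, tolerance = 1e-9)
      expect_equal(joint_covariance(st$posterior), jk$cov,
                   tolerance = 1e-9, ignore_attr = TRUE)
      b <- st$posterior
      m <- jk$mean
      P <- jk$cov
    }
  }
})

test_that("compiled runner reproduces the pure-R step recursion", {
  set.seed(104)
  sys <- piaf_system(w = c(1, -0.5), sigma_s = 2, sigma_p = 0.1)
  Q <- matrix(rnorm(300 * 2, sd = 0.2), 300, 2)
  tr <- simulate_trajectory(sys, Q, z0 = 0.3)
  fit <- piaf(tr, "piaf")
  b <- piaf_priors(2)
  for (n in 1:300) {
    st <- piaf_step(b, Q[n, ], tr$x[n], sigma_p = 0.1, sigma_s = 2)
    b <- st$posterior
    expect_equal(fit$mu_z_prior[n], st$prior$mu_z, tolerance = 1e-10)
    expect_equal(fit$mu_z_post[n], b$mu_z, tolerance = 1e-10)
    expect_equal(as.numeric(fit$mu_w[n, ]), b$mu_w, tolerance = 1e-10)
    expect_equal(as.numeric(fit$var_w_diag[n, ]), diag(b$Sigma_ww),
                 tolerance = 1e-10)
  }
  expect_equal(fit$Sigma_ww_final, b$Sigma_ww,
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("update contracts the state variance and preserves PSD", {
  set.seed(105)
  for (rep in 1:40) {
    Dq <- sample(1:3, 1)
    b <- random_belief(Dq)
    po <- piaf_update(b, rnorm(1), sigma_s = runif(1, 0.1, 2))
    expect_lt(po$Sigma_zz, b$Sigma_zz)
    J <- joint_covariance(po)
    ev <- eigen((J + t(J)) / 2, symmetric = TRUE, only.values = TRUE)$values
    expect_gte(min(ev), -1e-9 * sum(diag(J)))
    # weight variance never grows in an update
    expect_lte(max(diag(po$Sigma_ww) - diag(b$Sigma_ww)), 1e-12)
  }
})

test_that("applying a command reveals nothing about the weights", {
  set.seed(106)
  b <- random_belief(2)
  pr <- piaf_predict(b, c(0.3, -0.1), sigma_p = 0.2)
  expect_identical(pr$mu_w, b$mu_w)
  expect_identical(pr$Sigma_ww, b$Sigma_ww)
})

test_that("with certain weights the joint filter reduces to the known-w Kalman filter", {
  set.seed(107)
  w <- c(0.7, -1.2)
  b <- joint_belief(mu_z = 0.4, mu_w = w, Sigma_zz = 3,
                    Sigma_ww = matrix(0, 2, 2), Sigma_zw = c(0, 0))
  kb <- kalman_belief(0.4, 3)
  for (n in 1:50) {
    q <- rnorm(2, sd = 0.3)
    x <- rnorm(1)
    st <- piaf_step(b, q, x, sigma_p = 0.05, sigma_s = 1)
    ks <- kalman_step(kb, q, x, w, sigma_p = 0.05, sigma_s = 1)
    expect_equal(st$posterior$mu_z, ks$posterior$mu_z, tolerance = 1e-12)
    expect_equal(st$posterior$Sigma_zz, ks$posterior$Sigma_zz,
                 tolerance = 1e-12)
    expect_equal(st$posterior$mu_w, w, tolerance = 1e-12)
    b <- st$posterior
    kb <- ks$posterior
  }
})

test_that("reported state uncertainty is calibrated (credible-interval coverage)", {
  set.seed(108)
  sys <- piaf_system(w = 1, sigma_s = 2, sigma_p = 0.01)
  n_runs <- 400
  zsc <- numeric(n_runs)
  for (k in seq_len(n_runs)) {
    phi <- runif(1, 0, 2 * pi)
    tr <- simulate_trajectory(sys, control_sinusoidal(300, phi = phi),
                              z0 = sin(phi))
    fit <- piaf(tr, "piaf")
    zsc[k] <- (fit$mu_z_post[300] - tr$z[301]) / sqrt(fit$Sigma_zz_post[300])
  }
  coverage <- mean(abs(zsc) < qnorm(0.975))
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
})

test_that("degenerate updates error instead of dividing by zero", {
  b <- joint_belief(mu_z = 0, mu_w = 0, Sigma_zz = 0,
                    Sigma_ww = matrix(1), Sigma_zw = 0)
  expect_error(piaf_update(b, 1, sigma_s = 0), "degenerate")
  expect_error(piaf_predict(piaf_priors(2), qdot = 1, sigma_p = 0.1),
               "dimension")
})
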