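# Shared test oracles: random belief generation and brute-force Gaussian
# algebra, coded independently of the package's filter implementations.

# A random valid joint belief with a strictly positive-definite covariance.
random_belief <- function(Dq, scale = 1) {
  M <- matrix(rnorm((Dq + 1)^2), Dq + 1)
  C <- (crossprod(M) + 0.1 * diag(Dq + 1)) * scale
  joint_belief(mu_z = rnorm(1), mu_w = rnorm(Dq),
               Sigma_zz = C[1, 1],
               Sigma_ww = C[-1, -1, drop = FALSE],
               Sigma_zw = C[1, -1])
}

# Brute-force prediction oracle: push the joint Gaussian through the affine
# map (z, w) -> (z + qdot' w, w) and add the process noise.
oracle_predict <- function(mean, cov, qdot, sigma_p) {
  Dq <- length(qdot)
  A <- rbind(c(1, qdot), cbind(rep(0, Dq), diag(Dq)))
  list(mean = as.numeric(A %*% mean),
       cov = A %*% cov %*% t(A) + diag(c(sigma_p^2, rep(0, Dq)),
                                       nrow = Dq + 1))
}

# Brute-force conditioning oracle: form the (d+1)-dimensional joint Gaussian
# of (y, x) with x = y_1 + sensor noise and apply the generic
# partitioned-Gaussian conditional (Schur complement), nothing filter-shaped.
oracle_condition <- function(mean, cov, x, sigma_s) {
  d <- length(mean)
  mj <- c(mean, mean[1])
  Cj <- rbind(cbind(cov, cov[, 1]),
              c(cov[1, ], cov[1, 1] + sigma_s^2))
  S12 <- Cj[seq_len(d), d + 1]
  S22 <- Cj[d + 1, d + 1]
  list(mean = mj[seq_len(d)] + S12 * (x - mj[d + 1]) / S22,
       cov = Cj[seq_len(d), seq_len(d)] - tcrossprod(S12) / S22)
}

belief_mean <- function(b) c(b$mu_z, b$mu_w)

expect_belief_close <- function(b, mean, cov, tol = 1e-9) {
  expect_equal(belief_mean(b), mean, tolerance = tol, ignore_attr = TRUE)
  expect_equal(joint_covariance(b), cov, tolerance = tol, ignore_attr = TRUE)
}
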