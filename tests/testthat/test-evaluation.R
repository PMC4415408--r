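test_that("first_crossing handles the trivial cases", {
  expect_equal(first_crossing(rep(0.5, 10), 1), 1)
  expect_true(is.na(first_crossing(c(3, 2, 1.5), 1)))
  expect_error(first_crossing(numeric(0), 1), "empty")
  expect_error(first_crossing(c(1, 2), -1), "positive")
})

test_that("first_crossing interpolates on log-log axes", {
  cr <- first_crossing(c(10, 1, 0.1), 0.5)
  expect_gt(cr, 2)
  expect_lt(cr, 3)
  # oracle: dense re-gridding of the log-log interpolant
  li <- seq(log(2), log(3), length.out = 20001)
  lc <- seq(log(1), log(0.1), length.out = 20001)
  dense <- exp(li[which(lc <= log(0.5))[1]])
  expect_equal(cr, dense, tolerance = 1e-3)
})

test_that("speedup_factor is exact on closed-form curves and scale-invariant", {
  n <- 1:1000
  a <- 50
  k <- 7
  fast <- a / (k * n)
  slow <- a / n
  expect_equal(speedup_factor(slow, slow, 0.3), 1)
  expect_equal(speedup_factor(slow, fast, 0.3), k, tolerance = 1e-6)
  # multiplying the iteration axis by 13 leaves the ratio unchanged
  expect_equal(speedup_factor(slow, fast, 0.3, iterations = 13 * n), k,
               tolerance = 1e-6)
  expect_true(is.na(speedup_factor(slow, fast, 1e-9)))
})

test_that("metric operators are pure", {
  set.seed(301)
  curve <- cumprod(runif(500, 0.97, 1.01)) * 5
  a <- first_crossing(curve, 1)
  b <- first_crossing(curve, 1)
  expect_identical(a, b)
  d1 <- detect_stagnation(curve, 1e-3, window = 50)
  d2 <- detect_stagnation(curve, 1e-3, window = 50)
  expect_identical(d1, d2)
})

test_that("variance_calibration is the elementwise ratio and scales linearly", {
  base <- list(iteration = 1:5, mse_w = c(4, 3, 2, 1, 1),
               mse_z = c(2, 2, 2, 2, 2), est_var_w = rep(2, 5),
               est_var_z = rep(1, 5), n_runs = 10)
  cv <- structure(base, class = "mse_curves")
  vc <- variance_calibration(cv)
  expect_equal(vc$ratio_w, base$mse_w / 2)
  expect_equal(vc$ratio_z, rep(2, 5))
  halved <- cv
  halved$est_var_z <- cv$est_var_z / 2
  expect_equal(variance_calibration(halved)$ratio_z, 2 * vc$ratio_z)
  broken <- cv
  broken$est_var_z[3] <- 0
  expect_error(variance_calibration(broken), "zero")
})

test_that("detect_stagnation separates decaying from frozen curves", {
  set.seed(302)
  noise <- exp(rnorm(2000, 0, 0.05))
  # eps_slope above this noise floor: a 1/n decay has slope -1 per decade,
  # a frozen curve 0 +/- ~0.01; 0.05 separates them robustly
  decaying <- 10 / seq_len(2000) * noise
  d <- detect_stagnation(decaying, reference_floor = 10 / 2000, window = 100,
                         eps_slope = 0.05)
  expect_false(d$stagnated)
  frozen <- c(10 / (1:500), rep(10 / 500, 1500)) * noise
  d2 <- detect_stagnation(frozen, reference_floor = 10 / 500 / 100,
                          window = 100, eps_slope = 0.05)
  expect_true(d2$stagnated)
  expect_gte(d2$onset, 450)
  expect_lte(d2$onset, 800)   # onset near the freeze, within smoothing lag
  expect_error(detect_stagnation(1:10, 1, window = 11), "longer")
  expect_error(detect_stagnation(1:10, 1, window = 1), "at least 2")
})

test_that("plateau_mse is the trailing geometric mean", {
  expect_equal(plateau_mse(rep(3, 100)), 3)
  set.seed(303)
  curve <- exp(rnorm(1000))
  tail_idx <- 801:1000
  expect_equal(plateau_mse(curve, 0.2), exp(mean(log(curve[tail_idx]))),
               tolerance = 1e-12)
  expect_error(plateau_mse(numeric(0)), "empty")
  expect_error(plateau_mse(c(1, -1), 1), "positive")
})

test_that("near-noiseless known-weights filtering locks onto the state", {
  cfg <- experiment_config(method = "kalman", sigma_s = 1e-6, sigma_p = 0,
                           N = 50, n_runs = 1, seed = 5)
  cv <- mse_curves(cfg)
  expect_true(all(cv$mse_z < 1e-9))
})

test_that("Monte-Carlo error of the curves shrinks with the replicate count", {
  cfg1 <- experiment_config(method = "piaf", N = 200, n_runs = 100, seed = 31)
  cfg4 <- experiment_config(method = "piaf", N = 200, n_runs = 400, seed = 32)
  cv1 <- mse_curves(cfg1, keep_runs = TRUE)
  cv4 <- mse_curves(cfg4, keep_runs = TRUE)
  se1 <- sd(cv1$runs_w[, 200]) / sqrt(100)
  se4 <- sd(cv4$runs_w[, 200]) / sqrt(400)
  expect_equal(se1 / se4, 2, tolerance = 0.5)   # CLT scaling, loose band
  # the two independent estimates agree within their joint uncertainty
  expect_lt(abs(cv1$mse_w[200] - cv4$mse_w[200]),
            5 * sqrt(se1^2 + se4^2))
})

test_that("run seeds are deterministic, distinct and leave the RNG state alone", {
  s1 <- run_seeds(99, 50)
  s2 <- run_seeds(99, 50)
  expect_identical(s1, s2)
  expect_identical(anyDuplicated(s1), 0L)
  expect_true(all(s1 >= 1 & s1 < 2^31))
  set.seed(1234)
  before <- .Random.seed
  invisible(run_seeds(5, 10))
  expect_identical(.Random.seed, before)
})

test_that("mse_curves reproduces exactly from its master seed", {
  cfg <- experiment_config(method = "rls_kalman", N = 150, n_runs = 5,
                           seed = 77)
  a <- mse_curves(cfg)
  b <- mse_curves(cfg)
  expect_identical(a$mse_w, b$mse_w)
  expect_identical(a$mse_z, b$mse_z)
})
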