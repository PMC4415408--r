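#' Experiment configuration
#'
#' One named bundle of simulation and filtering settings for a Monte-Carlo
#' run: method, control regime, noise levels, priors, horizon, replicate
#' count, master seed and MSE thresholds. Defaults follow the bundled
#' experiments (w = 1, T = 50, sigma_s = 2, priors 0 / 1e4 / 0 / I / 0).
#'
#' @param method estimator name (see [piaf()]).
#' @param regime `"sinusoidal"` or `"gaussian"` control.
#' @param sigma_s,sigma_p noise standard deviations.
#' @param w true weight vector.
#' @param T control period in steps.
#' @param N horizon (steps), `>= 1`.
#' @param n_runs number of replicates, `>= 1`.
#' @param seed master seed; per-run substream seeds are derived from it so
#'   any run is reproducible in isolation (see [run_seeds()]).
#' @param priors a [joint_belief()] or `NULL` for [piaf_priors()].
#' @param thresholds MSE thresholds used by crossing-based summaries.
#' @param jitter,ridge passed to [piaf()].
#' @return Object of class `experiment_config`.
#' @export
experiment_config <- function(method = "piaf",
                              regime = c("sinusoidal", "gaussian"),
                              sigma_s = 2, sigma_p = 0.01, w = 1, T = 50,
                              N = 10000, n_runs = 1000, seed = 1,
                              priors = NULL,
                              thresholds = 10^c(-1.5, -2, -2.5, -3),
                              jitter = 0, ridge = 1e-8) {
  regime <- match.arg(regime)
  methods <- c("piaf", "kalman", "rls_piaf", "rls_kalman", "kalman_rls")
  if (!method %in% methods)
    stop("unknown method '", method, "'; must be one of ",
         paste(methods, collapse = ", "))
  if (sigma_s < 0) stop("'sigma_s' must be nonnegative")
  if (sigma_p < 0) stop("'sigma_p' must be nonnegative")
  if (N < 1) stop("'N' must be at least 1")
  if (n_runs < 1) stop("'n_runs' must be at least 1")
  if (T < 2) stop("'T' must be at least 2")
  w <- as.numeric(w)
  if (is.null(priors)) priors <- piaf_priors(length(w))
  validate_belief(priors)
  structure(list(method = method, regime = regime,
                 sigma_s = as.numeric(sigma_s), sigma_p = as.numeric(sigma_p),
                 w = w, T = as.numeric(T), N = as.integer(N),
                 n_runs = as.integer(n_runs), seed = as.integer(seed),
                 priors = priors, thresholds = as.numeric(thresholds),
                 jitter = as.numeric(jitter), ridge = as.numeric(ridge)),
            class = "experiment_config")
}

#' @export
print.experiment_config <- function(x, ...) {
  cat("Experiment config: method '", x$method, "', ", x$regime,
      " control (T = ", x$T, ")\n", sep = "")
  cat("  sigma_s = ", x$sigma_s, ", sigma_p = ", x$sigma_p,
      ", w = ", paste(signif(x$w, 4), collapse = ", "), "\n", sep = "")
  cat("  N = ", x$N, ", n_runs = ", x$n_runs, ", seed = ", x$seed, "\n",
      sep = "")
  invisible(x)
}

#' Per-run substream seeds
#'
#' Derives `n_runs` reproducible seeds from a master seed: the master seed
#' initializes R's generator once and a seed table is drawn from it, so run
#' `k` can be reproduced in isolation from `run_seeds(seed, n)[k]`.
#'
#' @param seed master seed.
#' @param n_runs number of runs.
#' @return Integer vector of length `n_runs`.
#' @export
run_seeds <- function(seed, n_runs) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n_runs)
}

simulate_run <- function(config, run_seed) {
  set.seed(run_seed)
  phi <- runif(1, 0, 2 * pi)
  ctrl <- if (config$regime == "sinusoidal")
    control_sinusoidal(config$N, T = config$T, phi = phi)
  else
    control_gaussian(config$N, T = config$T, D_q = length(config$w))
  sys <- piaf_system(w = config$w, sigma_s = config$sigma_s,
                     sigma_p = config$sigma_p)
  simulate_trajectory(sys, ctrl, z0 = sin(phi))
}

fit_run <- function(config, trajectory) {
  piaf(trajectory, method = config$method, priors = config$priors,
       jitter = config$jitter, ridge = config$ridge)
}

#' Monte-Carlo MSE curves
#'
#' Runs `n_runs` seeded replicates of the configured method on freshly
#' simulated trajectories and averages, per iteration, the squared weight
#' error \eqn{|\mu_w - w|^2}, the squared state error
#' \eqn{(\mu_{z,n|n} - z_n)^2}, and the filter's own reported variances
#' (trace of \eqn{\Sigma_{ww}}, \eqn{\Sigma_{zz}}).
#'
#' @param config an [experiment_config()].
#' @param keep_runs if `TRUE`, also return the per-run squared-error curves
#'   (matrices `n_runs x N`) needed for per-run stagnation diagnosis.
#' @return Object of class `mse_curves`: list with `iteration`, `mse_w`,
#'   `mse_z`, `est_var_w`, `est_var_z`, `n_runs`, the `config`, and
#'   optionally `runs_w`, `runs_z`.
#' @examples
#' cfg <- experiment_config(method = "piaf", N = 300, n_runs = 20, seed = 1)
#' cv <- mse_curves(cfg)
#' plot(cv)
#' @export
mse_curves <- function(config, keep_runs = FALSE) {
  stopifnot(inherits(config, "experiment_config"))
  N <- config$N
  seeds <- run_seeds(config$seed, config$n_runs)
  acc_w <- acc_z <- acc_vw <- acc_vz <- numeric(N)
  runs_w <- if (keep_runs) matrix(0, config$n_runs, N) else NULL
  runs_z <- if (keep_runs) matrix(0, config$n_runs, N) else NULL
  w_true <- config$w
  for (k in seq_len(config$n_runs)) {
    tr <- simulate_run(config, seeds[k])
    fit <- fit_run(config, tr)
    err_w <- rowSums((fit$mu_w - matrix(w_true, N, length(w_true),
                                        byrow = TRUE))^2)
    err_z <- (fit$mu_z_post - tr$z[-1L])^2
    acc_w <- acc_w + err_w
    acc_z <- acc_z + err_z
    acc_vw <- acc_vw + rowSums(fit$var_w_diag)
    acc_vz <- acc_vz + fit$Sigma_zz_post
    if (keep_runs) { runs_w[k, ] <- err_w; runs_z[k, ] <- err_z }
  }
  n <- config$n_runs
  structure(list(iteration = seq_len(N), mse_w = acc_w / n, mse_z = acc_z / n,
                 est_var_w = acc_vw / n, est_var_z = acc_vz / n,
                 n_runs = n, config = config,
                 runs_w = runs_w, runs_z = runs_z),
            class = "mse_curves")
}

#' @export
as.data.frame.mse_curves <- function(x, ...) {
  data.frame(iteration = x$iteration, mse_w = x$mse_w, mse_z = x$mse_z,
             est_var_w = x$est_var_w, est_var_z = x$est_var_z,
             n_runs = x$n_runs)
}

#' @export
print.mse_curves <- function(x, ...) {
  cat("Monte-Carlo MSE curves: method '", x$config$method, "', ",
      x$n_runs, " runs x ", length(x$iteration), " steps\n", sep = "")
  cat("  final mse_w = ", signif(tail(x$mse_w, 1), 4),
      ", final mse_z = ", signif(tail(x$mse_z, 1), 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.mse_curves <- function(x, channel = c("w", "z"), ...) {
  channel <- match.arg(channel)
  mse <- if (channel == "w") x$mse_w else x$mse_z
  ev <- if (channel == "w") x$est_var_w else x$est_var_z
  plot(x$iteration, mse, log = "xy", type = "l", col = "blue",
       xlab = "iteration", ylab = paste0("MSE(", channel, ")"), ...)
  lines(x$iteration, ev, col = "blue", lty = 2)
  legend("bottomleft", bty = "n", lty = c(1, 2), col = "blue",
         legend = c("observed MSE", "estimated variance"))
  invisible(x)
}

#' First threshold crossing of a decaying curve
#'
#' First iteration at which the curve falls to or below `threshold`, refined
#' by log-log linear interpolation between the bracketing iterations (the
#' curves are read on double-logarithmic axes). Returns `NA` ("not reached")
#' if the curve never crosses.
#'
#' @param curve per-iteration values.
#' @param threshold positive threshold.
#' @param iterations iteration axis (default `seq_along(curve)`).
#' @return Fractional iteration of first crossing, or `NA_real_`.
#' @examples
#' first_crossing(c(10, 1, 0.1), 0.5)  # between iterations 2 and 3
#' @export
first_crossing <- function(curve, threshold, iterations = seq_along(curve)) {
  if (length(curve) == 0L) stop("empty curve")
  if (!is.numeric(threshold) || threshold <= 0)
    stop("'threshold' must be positive")
  i <- which(curve <= threshold)[1L]
  if (is.na(i)) return(NA_real_)
  if (i == 1L) return(iterations[1L])
  c0 <- curve[i - 1L]; c1 <- curve[i]
  if (!is.finite(log(c1)) || c1 <= 0)  # hit zero: report the bracketing step
    return(iterations[i])
  f <- (log(threshold) - log(c0)) / (log(c1) - log(c0))
  exp(log(iterations[i - 1L]) + f * (log(iterations[i]) - log(iterations[i - 1L])))
}

#' Sample-count speedup factor between two curves
#'
#' Ratio of first-crossing iterations, slow over fast. `NA` if either curve
#' never reaches the threshold.
#'
#' @param curve_slow,curve_fast per-iteration MSE curves.
#' @param threshold positive threshold.
#' @param iterations iteration axis shared by both curves.
#' @export
speedup_factor <- function(curve_slow, curve_fast, threshold,
                           iterations = seq_along(curve_slow)) {
  cs <- first_crossing(curve_slow, threshold, iterations)
  cf <- first_crossing(curve_fast, threshold, iterations)
  if (is.na(cs) || is.na(cf)) return(NA_real_)
  cs / cf
}

#' Variance calibration diagnostic
#'
#' Per-iteration ratio of the Monte-Carlo observed MSE to the filter's own
#' mean reported variance, for the state and weight channels. A ratio above 1
#' means the filter under-estimates its error (overconfidence); below 1,
#' over-estimation.
#'
#' @param curves an [mse_curves()] result.
#' @return Data frame with columns `iteration`, `ratio_z`, `ratio_w`.
#' @export
variance_calibration <- function(curves) {
  stopifnot(inherits(curves, "mse_curves"))
  if (any(curves$est_var_z <= 0) || any(curves$est_var_w <= 0))
    stop("estimated variance is zero at some iteration; ratio undefined")
  data.frame(iteration = curves$iteration,
             ratio_z = curves$mse_z / curves$est_var_z,
             ratio_w = curves$mse_w / curves$est_var_w)
}

#' Detect learning stagnation in an error curve
#'
#' Flags a run whose error curve stops decreasing while remaining well above
#' an achievable reference floor. The curve is first smoothed with a rolling
#' mean of `window` iterations. The run is flagged as stagnant when, over the
#' trailing octave of iterations (the smoothed points whose iteration exceeds
#' half the final iteration), (i) the least-squares slope of the smoothed
#' curve on log-log axes exceeds `-eps_slope` per decade and (ii) the
#' smoothed curve stays above `factor * reference_floor`. Slopes are measured
#' over the trailing octave rather than a fixed point count because a
#' per-decade slope cannot be resolved over a vanishing log-span. The onset
#' is the first iteration from which both conditions hold through the end;
#' the slope condition at an interior point is the secant slope from that
#' point to the end, with the denominator floored at the octave span.
#'
#' @param curve per-iteration (squared) error values of one run.
#' @param reference_floor achievable error level (e.g. the trailing mean
#'   error of a well-behaved method).
#' @param factor multiple of the floor above which a plateau counts as
#'   stagnation (default 10).
#' @param window smoothing window in iterations, `>= 2`.
#' @param eps_slope slope tolerance per decade (default 1e-3).
#' @param iterations iteration axis.
#' @return List with `stagnated` (logical), `onset` (iteration or `NA`) and
#'   `trailing_slope` (per decade).
#' @export
detect_stagnation <- function(curve, reference_floor, factor = 10,
                              window = 100, eps_slope = 1e-3,
                              iterations = seq_along(curve)) {
  N <- length(curve)
  if (window < 2) stop("'window' must be at least 2")
  if (window > N) stop("'window' is longer than the curve")
  cs <- cumsum(c(0, curve))
  smooth <- (cs[(window + 1):(N + 1)] - cs[1:(N - window + 1)]) / window
  idx <- seq.int(window, N)           # iteration of each smoothed value
  eps0 <- .Machine$double.xmin
  lsm <- log10(pmax(smooth, eps0))
  li <- log10(iterations[idx])
  k <- length(lsm)
  octave <- log10(2)

  # flag: regression slope over the trailing octave of smoothed points
  tail_idx <- which(li > li[k] - octave)
  if (length(tail_idx) < 2L) tail_idx <- c(max(1L, k - 1L), k)
  xt <- li[tail_idx]
  yt <- lsm[tail_idx]
  denom <- sum((xt - mean(xt))^2)
  trailing_slope <- if (denom > 0)
    sum((xt - mean(xt)) * (yt - mean(yt))) / denom else 0
  above <- smooth > factor * reference_floor
  flagged <- (trailing_slope > -eps_slope) && all(above[tail_idx])
  if (!flagged)
    return(list(stagnated = FALSE, onset = NA_real_,
                trailing_slope = trailing_slope))

  # onset: secant slope from each point to the end, denominator floored at
  # the octave span (finer spans are unresolvable)
  secant <- (lsm[k] - lsm) / pmax(li[k] - li, octave)
  cond <- (secant > -eps_slope) & above
  holds_to_end <- rev(cumprod(rev(cond))) > 0
  onset <- iterations[idx[which(holds_to_end)[1L]]]
  list(stagnated = TRUE, onset = onset, trailing_slope = trailing_slope)
}

#' Plateau level of an error curve
#'
#' Geometric mean of the curve over its trailing fraction of iterations.
#'
#' @param curve per-iteration values (positive).
#' @param trailing_fraction fraction in (0, 1] of iterations to average.
#' @return Scalar plateau value.
#' @export
plateau_mse <- function(curve, trailing_fraction = 0.2) {
  if (length(curve) == 0L) stop("empty curve")
  if (trailing_fraction <= 0 || trailing_fraction > 1)
    stop("'trailing_fraction' must be in (0, 1]")
  n <- length(curve)
  idx <- seq.int(max(1L, n - ceiling(trailing_fraction * n) + 1L), n)
  v <- curve[idx]
  if (any(v <= 0)) stop("curve must be positive over the trailing window")
  exp(mean(log(v)))
}
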