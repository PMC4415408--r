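#' Define the generative system
#'
#' The world model assumed throughout the package: a scalar latent state
#' \eqn{z_n} performs a driven random walk
#' \eqn{z_n = z_{n-1} + \dot q_n^T w + \epsilon_{p,n}} with process noise
#' \eqn{\epsilon_{p,n} \sim N(0, \sigma_p^2)}, and is observed through
#' \eqn{x_n = z_n + \epsilon_{s,n}} with sensor noise
#' \eqn{\epsilon_{s,n} \sim N(0, \sigma_s^2)}. The commands \eqn{\dot q_n}
#' (efference copies) are known to the filter; the weight vector \eqn{w} is
#' not.
#'
#' @param w true command-to-state weight vector (length `D_q`). Default 1,
#'   the scalar setting used in all bundled experiment presets.
#' @param sigma_s sensor-noise standard deviation (state units), `>= 0`.
#' @param sigma_p process-noise standard deviation (state units), `>= 0`.
#' @return An object of class `piaf_system` with fields `w`, `sigma_s`,
#'   `sigma_p` and `D_q = length(w)`.
#' @seealso [simulate_trajectory()], [piaf()]
#' @examples
#' sys <- piaf_system(w = 1, sigma_s = 2, sigma_p = 0.01)
#' sys
#' @export
piaf_system <- function(w = 1, sigma_s = 2, sigma_p = 0.01) {
  w <- as.numeric(w)
  if (length(w) < 1L || anyNA(w)) stop("'w' must be a numeric vector of length >= 1")
  if (!is.numeric(sigma_s) || length(sigma_s) != 1L || is.na(sigma_s) || sigma_s < 0)
    stop("'sigma_s' must be a single nonnegative number")
  if (!is.numeric(sigma_p) || length(sigma_p) != 1L || is.na(sigma_p) || sigma_p < 0)
    stop("'sigma_p' must be a single nonnegative number")
  structure(list(w = w, sigma_s = sigma_s, sigma_p = sigma_p,
                 D_q = length(w)),
            class = "piaf_system")
}

#' @export
print.piaf_system <- function(x, ...) {
  cat("Linear forward-model system (D_q =", x$D_q, ")\n")
  cat("  w       =", paste(signif(x$w, 4), collapse = ", "), "\n")
  cat("  sigma_s =", x$sigma_s, " sigma_p =", x$sigma_p, "\n")
  invisible(x)
}

#' Sinusoidal (continuous) control sequence
#'
#' Scalar commands \eqn{\dot q_n = \omega \cos(\omega n + \phi)} with
#' \eqn{\omega = 2\pi/T}. Under weights `w = 1` and no process noise the
#' resulting state approximates a unit-amplitude sinusoid
#' \eqn{z_n \approx \sin(\omega n + \phi)} when started at
#' \eqn{z_0 = \sin(\phi)}.
#'
#' @param N number of steps, `>= 1`.
#' @param T period in steps, `>= 2`. Default 50.
#' @param phi start phase in radians. Default 0.
#' @return An `N x 1` command matrix with attributes `regime`, `T`, `phi`,
#'   `omega`.
#' @examples
#' q <- control_sinusoidal(100, T = 50, phi = 0)
#' sum(q[1:50, 1])  # full-period cosine sum is 0
#' @export
control_sinusoidal <- function(N, T = 50, phi = 0) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1)
    stop("'N' must be a positive number of steps")
  if (!is.numeric(T) || length(T) != 1L || T < 2)
    stop("'T' must be a period of at least 2 steps")
  N <- as.integer(N)
  omega <- 2 * pi / T
  q <- matrix(omega * cos(omega * seq_len(N) + phi), ncol = 1L)
  structure(q, regime = "sinusoidal", T = T, phi = phi, omega = omega)
}

#' Random (Gaussian) control sequence
#'
#' Commands drawn i.i.d. from \eqn{N(0, \omega^2/2)} per component, matching
#' the mean and variance of the sinusoidal control with the same period
#' \eqn{T} (\eqn{\omega = 2\pi/T}). Draws come from R's current random
#' generator; seed with [set.seed()] for reproducibility.
#'
#' @inheritParams control_sinusoidal
#' @param D_q command dimension. Default 1.
#' @return An `N x D_q` command matrix with attributes `regime`, `T`, `omega`.
#' @examples
#' set.seed(1)
#' q <- control_gaussian(1000, T = 50)
#' var(q)  # approx (2*pi/50)^2 / 2
#' @export
control_gaussian <- function(N, T = 50, D_q = 1) {
  if (!is.numeric(N) || length(N) != 1L || is.na(N) || N < 1)
    stop("'N' must be a positive number of steps")
  N <- as.integer(N)
  omega <- 2 * pi / T
  q <- matrix(rnorm(N * D_q, mean = 0, sd = omega / sqrt(2)), nrow = N, ncol = D_q)
  structure(q, regime = "gaussian", T = T, omega = omega)
}

#' Simulate a trajectory from the generative system
#'
#' Applies the state transition and measurement model step by step:
#' \eqn{z_n = z_{n-1} + \dot q_n^T w + \epsilon_{p,n}},
#' \eqn{x_n = z_n + \epsilon_{s,n}}. One filter iteration later consumes the
#' pair \eqn{(\dot q_n, x_n)}: the command acts on the transition
#' \eqn{(n-1) \to n} and the measurement is taken after it. Noise draws come
#' from R's current random generator.
#'
#' @param system a [piaf_system()].
#' @param control an `N x D_q` command matrix ([control_sinusoidal()],
#'   [control_gaussian()], or any numeric matrix).
#' @param z0 initial state. The bundled experiments use `z0 = sin(phi)` with
#'   the control's start phase.
#' @return An object of class `piaf_trajectory`: list with `z` (length
#'   `N + 1`, indices 0..N), `x` and `qdot` (length/rows `N`), `z0`, `N`, and
#'   the generating `system`.
#' @examples
#' sys <- piaf_system(w = 1, sigma_s = 2, sigma_p = 0)
#' set.seed(42)
#' tr <- simulate_trajectory(sys, control_sinusoidal(200), z0 = 0)
#' head(as.data.frame(tr))
#' @export
simulate_trajectory <- function(system, control, z0 = 0) {
  stopifnot(inherits(system, "piaf_system"))
  control <- as.matrix(control)
  N <- nrow(control)
  if (N < 1L) stop("'control' must contain at least one command")
  if (ncol(control) != system$D_q)
    stop("command dimension (", ncol(control), ") does not match length(w) = ",
         system$D_q)
  drift <- as.numeric(control %*% system$w)
  eps_p <- if (system$sigma_p > 0) rnorm(N, 0, system$sigma_p) else numeric(N)
  z <- z0 + cumsum(drift + eps_p)
  eps_s <- if (system$sigma_s > 0) rnorm(N, 0, system$sigma_s) else numeric(N)
  structure(list(z = c(z0, z), x = z + eps_s, qdot = control,
                 z0 = z0, N = N, system = system),
            class = "piaf_trajectory")
}

#' Simulate trajectories from a system object
#'
#' [simulate()] method for [piaf_system()] objects: draws `nsim` independent
#' trajectories under the given control regime, each with its own start phase
#' \eqn{\phi \sim U[0, 2\pi)} and starting state \eqn{z_0 = \sin(\phi)} (the
#' convention of the bundled experiments).
#'
#' @param object a [piaf_system()].
#' @param nsim number of trajectories.
#' @param seed optional seed passed to [set.seed()].
#' @param N horizon (steps).
#' @param regime `"sinusoidal"` or `"gaussian"`.
#' @param T control period in steps.
#' @param ... unused.
#' @return A list of `piaf_trajectory` objects (a single trajectory if
#'   `nsim = 1`).
#' @examples
#' tr <- simulate(piaf_system(), nsim = 1, seed = 7, N = 100)
#' tr
#' @export
simulate.piaf_system <- function(object, nsim = 1, seed = NULL,
                                 N = 1000, regime = c("sinusoidal", "gaussian"),
                                 T = 50, ...) {
  regime <- match.arg(regime)
  if (!is.null(seed)) set.seed(seed)
  out <- vector("list", nsim)
  for (k in seq_len(nsim)) {
    phi <- runif(1, 0, 2 * pi)
    ctrl <- if (regime == "sinusoidal") control_sinusoidal(N, T = T, phi = phi)
            else control_gaussian(N, T = T, D_q = object$D_q)
    out[[k]] <- simulate_trajectory(object, ctrl, z0 = sin(phi))
  }
  if (nsim == 1) out[[1]] else out
}

#' @export
print.piaf_trajectory <- function(x, ...) {
  cat("Simulated trajectory: N =", x$N, "steps, D_q =", ncol(x$qdot), "\n")
  cat("  z range [", signif(min(x$z), 3), ",", signif(max(x$z), 3), "],",
      "x sd", signif(sd(x$x), 3), "\n")
  invisible(x)
}

#' @export
as.data.frame.piaf_trajectory <- function(x, ...) {
  Dq <- ncol(x$qdot)
  qd <- rbind(matrix(NA_real_, 1, Dq), x$qdot)
  out <- data.frame(step = 0:x$N, z = x$z, x = c(NA_real_, x$x))
  for (j in seq_len(Dq)) out[[paste0("qdot_", j - 1L)]] <- qd[, j]
  out
}

#' @export
plot.piaf_trajectory <- function(x, ...) {
  plot(seq_len(x$N), x$x, pch = 4, col = "grey50", cex = 0.5,
       xlab = "step", ylab = "state", ...)
  lines(0:x$N, x$z, col = "blue", lwd = 2)
  legend("topright", bty = "n", legend = c("true z", "measurements x"),
         col = c("blue", "grey50"), lty = c(1, NA), pch = c(NA, 4))
  invisible(x)
}

#' Noise-to-signal MSE ratio of an observation channel
#'
#' Ratio of the noise mean square to the signal mean square for one of the
#' two channels a learner can observe: the raw state channel (`x` vs `z`,
#' noise variance \eqn{\sigma_s^2}) or the differenced channel
#' (\eqn{\dot x_n = x_n - x_{n-1}} vs \eqn{\dot z_n}, whose noise
#' \eqn{\epsilon_{s,n} - \epsilon_{s,n-1} + \epsilon_{p,n}} has variance
#' \eqn{2\sigma_s^2 + \sigma_p^2}). Differencing destroys most of the
#' signal-to-noise ratio, which is why naive RLS on raw differences starts so
#' poorly.
#'
#' @param system a [piaf_system()].
#' @param signal the noise-free signal of the chosen channel: the latent
#'   states \eqn{z_n} for `"state"`, the per-step changes
#'   \eqn{\dot q_n^T w} for `"differenced"`. Obtain it from a noise-free
#'   re-simulation or analytically (see [ideal_sinusoid()]).
#' @param channel `"state"` or `"differenced"`.
#' @return The scalar ratio noise MSE / signal MSE.
#' @examples
#' sys <- piaf_system(w = 1, sigma_s = 2, sigma_p = 0)
#' mse_snr(sys, ideal_sinusoid(500, T = 50), "state")  # = 8
#' @export
mse_snr <- function(system, signal, channel = c("state", "differenced")) {
  stopifnot(inherits(system, "piaf_system"))
  channel <- match.arg(channel)
  ms <- mean(signal^2)
  if (ms == 0) stop("signal has zero power; ratio undefined")
  noise_var <- switch(channel,
    state = system$sigma_s^2,
    differenced = 2 * system$sigma_s^2 + system$sigma_p^2)
  noise_var / ms
}

#' Ideal unit-amplitude sinusoid
#'
#' The closed-form state \eqn{\sin(\omega n + \phi)} that the noise-free
#' system approaches under sinusoidal control with `w = 1`; over whole
#' periods its mean square is exactly 1/2 on the discrete lattice.
#'
#' @inheritParams control_sinusoidal
#' @return Numeric vector of length `N`.
#' @export
ideal_sinusoid <- function(N, T = 50, phi = 0) {
  omega <- 2 * pi / T
  sin(omega * seq_len(as.integer(N)) + phi)
}
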