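#' @export
print.piaf_fit <- function(x, ...) {
  cat("Online filter fit: method '", x$method, "', N = ", x$N,
      " steps, D_q = ", x$D_q, "\n", sep = "")
  cf <- coef(x)
  sdw <- sqrt(pmax(x$var_w_diag[x$N, ], 0))
  cat("  final weight estimate: ",
      paste(sprintf("%s = %.4g (sd %.3g)", names(cf), cf, sdw),
            collapse = ", "), "\n", sep = "")
  cat("  final state estimate:  mu_z = ", signif(x$mu_z_post[x$N], 5),
      " (sd ", signif(sqrt(x$Sigma_zz_post[x$N]), 3), ")\n", sep = "")
  invisible(x)
}

#' Final weight estimate
#'
#' @param object a [piaf()] fit.
#' @param ... unused.
#' @return Named numeric vector `w1..wD` with the last posterior weight mean.
#' @export
coef.piaf_fit <- function(object, ...) {
  cf <- as.numeric(object$mu_w[object$N, ])
  names(cf) <- paste0("w", seq_len(object$D_q))
  cf
}

#' @export
fitted.piaf_fit <- function(object, ...) object$mu_z_post

#' Filter residuals
#'
#' `"innovation"` residuals are the one-step-ahead prediction errors
#' \eqn{x_n - \mu_{z,n|n-1}} that drive both the state and the weight
#' updates; `"response"` residuals are \eqn{x_n - \mu_{z,n|n}}.
#'
#' @param object a [piaf()] fit.
#' @param type residual type.
#' @param ... unused.
#' @export
residuals.piaf_fit <- function(object, type = c("innovation", "response"), ...) {
  type <- match.arg(type)
  x <- object$trajectory$x
  if (type == "innovation") x - object$mu_z_prior else x - object$mu_z_post
}

#' Predict from a fitted filter
#'
#' Without `newcontrol`, returns the one-step-ahead prior means
#' \eqn{\mu_{z,n|n-1}} over the fitted trajectory. With `newcontrol` (an
#' `h x D_q` command matrix), forecasts the state `h` steps past the end of
#' the trajectory using the final joint belief; the forecast variance
#' accumulates process noise and the weight uncertainty mapped through the
#' cumulated commands (including, for the joint methods, the cross term).
#'
#' @param object a [piaf()] fit.
#' @param newcontrol optional future command matrix.
#' @param se.fit if `TRUE` also return standard errors.
#' @param ... unused.
#' @return Numeric vector, or list with `fit` and `se.fit`.
#' @export
predict.piaf_fit <- function(object, newcontrol = NULL, se.fit = FALSE, ...) {
  if (is.null(newcontrol)) {
    out <- object$mu_z_prior
    if (!se.fit) return(out)
    return(list(fit = out, se.fit = sqrt(pmax(object$Sigma_zz_prior, 0))))
  }
  Qn <- as.matrix(newcontrol)
  if (ncol(Qn) != object$D_q) stop("newcontrol must have D_q columns")
  wf <- as.numeric(object$mu_w[object$N, ])
  fit <- object$mu_z_post[object$N] + cumsum(as.numeric(Qn %*% wf))
  if (!se.fit) return(fit)
  Sww <- object$Sigma_ww_final
  Szw <- object$Sigma_zw_final
  Qc <- apply(Qn, 2, cumsum)
  if (is.null(dim(Qc))) Qc <- matrix(Qc, nrow = nrow(Qn))
  h <- seq_len(nrow(Qn))
  var_h <- object$Sigma_zz_post[object$N] + h * object$sigma_p^2 +
    rowSums((Qc %*% Sww) * Qc) + 2 * as.numeric(Qc %*% Szw)
  list(fit = fit, se.fit = sqrt(pmax(var_h, 0)))
}

#' @export
logLik.piaf_fit <- function(object, ...) {
  s2 <- if (object$method == "rls_piaf") 2 * object$sigma_s^2 else object$sigma_s^2
  v <- object$Sigma_zz_prior + s2
  ll <- sum(dnorm(object$trajectory$x, object$mu_z_prior, sqrt(v), log = TRUE))
  structure(ll, df = object$D_q + 1, nobs = object$N, class = "logLik")
}

#' @export
summary.piaf_fit <- function(object, trailing = 0.3, ...) {
  N <- object$N
  cf <- coef(object)
  sdw <- sqrt(pmax(object$var_w_diag[N, ], 0))
  tab <- cbind(Estimate = cf, `Std. dev.` = sdw)
  tail_idx <- seq.int(max(1L, floor(N * (1 - trailing)) + 1L), N)
  z <- object$trajectory$z
  rms_tail <- w_err <- NA_real_
  if (!is.null(z)) {
    rms_tail <- sqrt(mean((object$mu_z_post[tail_idx] - z[tail_idx + 1L])^2))
  }
  truth <- object$trajectory$system$w
  if (!is.null(truth) && object$method != "kalman")
    w_err <- sqrt(sum((cf - truth)^2))
  structure(list(method = object$method, N = N, D_q = object$D_q,
                 coefficients = tab, rms_tail = rms_tail,
                 trailing = trailing, w_error = w_err,
                 logLik = as.numeric(logLik(object)),
                 sigma_s = object$sigma_s, sigma_p = object$sigma_p),
            class = "summary.piaf_fit")
}

#' @export
print.summary.piaf_fit <- function(x, ...) {
  cat("Method: ", x$method, "  (N = ", x$N, ", sigma_s = ", x$sigma_s,
      ", sigma_p = ", x$sigma_p, ")\n\nWeights:\n", sep = "")
  print(signif(x$coefficients, 5))
  if (!is.na(x$w_error))
    cat("\n|w_hat - w| (vs simulating system):", signif(x$w_error, 4), "\n")
  if (!is.na(x$rms_tail))
    cat("Trailing-", round(100 * x$trailing), "% RMS state-tracking error: ",
        signif(x$rms_tail, 4), "\n", sep = "")
  cat("Innovation log-likelihood:", signif(x$logLik, 6), "\n")
  invisible(x)
}

#' Plot a fitted filter
#'
#' True state (when available), measurements, posterior state estimate and
#' the two-standard-deviation credible band.
#'
#' @param x a [piaf()] fit.
#' @param steps which steps to show (default all).
#' @param ... further arguments to [plot()].
#' @export
plot.piaf_fit <- function(x, steps = seq_len(x$N), ...) {
  tr <- x$trajectory
  mu <- x$mu_z_post[steps]
  s <- sqrt(pmax(x$Sigma_zz_post[steps], 0))
  ylim <- range(mu + 2 * s, mu - 2 * s, tr$x[steps], finite = TRUE)
  plot(steps, tr$x[steps], pch = 4, col = "grey60", cex = 0.4,
       xlab = "step", ylab = "state", ylim = ylim, ...)
  polygon(c(steps, rev(steps)), c(mu + 2 * s, rev(mu - 2 * s)),
          col = adjustcolor("gold", 0.4), border = NA)
  if (!is.null(tr$z)) lines(steps, tr$z[steps + 1L], col = "blue", lwd = 1.5)
  lines(steps, mu, col = "red", lwd = 1.5)
  legend("topright", bty = "n",
         legend = c("true z", "estimate", "x", "+/- 2 sd"),
         col = c("blue", "red", "grey60", "gold"),
         lty = c(1, 1, NA, NA), pch = c(NA, NA, 4, 15))
  invisible(x)
}

#' Per-step records of a fit as a data frame
#'
#' Columns: `method`, `step`, `mu_z_prior`, `mu_z_post`, `Sigma_zz_prior`,
#' `Sigma_zz_post`, then `mu_w_0..`, `var_w_0..` and (joint methods)
#' `Sigma_zw_0..`. Suitable for CSV export.
#'
#' @param x a [piaf()] fit.
#' @param ... unused.
#' @export
as.data.frame.piaf_fit <- function(x, ...) {
  out <- data.frame(method = x$method, step = seq_len(x$N),
                    mu_z_prior = x$mu_z_prior, mu_z_post = x$mu_z_post,
                    Sigma_zz_prior = x$Sigma_zz_prior,
                    Sigma_zz_post = x$Sigma_zz_post)
  for (j in seq_len(x$D_q)) {
    out[[paste0("mu_w_", j - 1L)]] <- x$mu_w[, j]
    out[[paste0("var_w_", j - 1L)]] <- x$var_w_diag[, j]
  }
  if (!is.null(x[["Sigma_zw"]]))
    for (j in seq_len(x$D_q))
      out[[paste0("Sigma_zw_", j - 1L)]] <- x[["Sigma_zw"]][, j]
  out
}
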