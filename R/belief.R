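#' Joint Gaussian belief over state and weights
#'
#' Sufficient statistics of the filter's joint Gaussian posterior over the
#' scalar state \eqn{z} and the weight vector \eqn{w}: means \eqn{\mu_z},
#' \eqn{\mu_w}, state variance \eqn{\Sigma_{zz}}, weight covariance
#' \eqn{\Sigma_{ww}} and the state-weight cross-covariance row vector
#' \eqn{\Sigma_{zw}}. The cross-covariance is the quantity that the ad-hoc
#' filter/learner couplings discard.
#'
#' @param mu_z state mean.
#' @param mu_w weight mean vector (length `D_q`).
#' @param Sigma_zz state variance, `>= 0`.
#' @param Sigma_ww weight covariance matrix (`D_q x D_q`, symmetric PSD).
#' @param Sigma_zw cross-covariance (length `D_q`).
#' @return An object of class `joint_belief`.
#' @seealso [piaf_priors()] for the default prior used in the experiments.
#' @export
joint_belief <- function(mu_z = 0, mu_w = 0, Sigma_zz = 1e4,
                         Sigma_ww = diag(length(mu_w)), Sigma_zw = 0 * mu_w) {
  mu_w <- as.numeric(mu_w)
  Dq <- length(mu_w)
  Sigma_ww <- as.matrix(Sigma_ww)
  Sigma_zw <- as.numeric(Sigma_zw)
  b <- structure(list(mu_z = as.numeric(mu_z), mu_w = mu_w,
                      Sigma_zz = as.numeric(Sigma_zz),
                      Sigma_ww = Sigma_ww, Sigma_zw = Sigma_zw,
                      D_q = Dq),
                 class = "joint_belief")
  validate_belief(b)
  b
}

#' Validate a joint belief
#'
#' Checks dimensions and that the full `(1 + D_q) x (1 + D_q)` joint
#' covariance is symmetric positive semidefinite, up to a relative eigenvalue
#' tolerance of `1e-9` of its trace.
#'
#' @param belief a [joint_belief()].
#' @return `belief`, invisibly; errors on violation.
#' @export
validate_belief <- function(belief) {
  stopifnot(inherits(belief, "joint_belief"))
  Dq <- belief$D_q
  if (length(belief$mu_z) != 1L || length(belief$Sigma_zz) != 1L)
    stop("mu_z and Sigma_zz must be scalars")
  if (!all(dim(belief$Sigma_ww) == c(Dq, Dq)))
    stop("Sigma_ww must be ", Dq, " x ", Dq)
  if (length(belief$Sigma_zw) != Dq)
    stop("Sigma_zw must have length ", Dq)
  J <- joint_covariance(belief)
  if (max(abs(J - t(J))) > 1e-8 * (1 + max(abs(J))))
    stop("joint covariance is not symmetric")
  ev <- eigen((J + t(J)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-9 * max(sum(diag(J)), 1))
    stop("joint covariance is not positive semidefinite (min eigenvalue ",
         signif(min(ev), 3), ")")
  invisible(belief)
}

#' Assemble the full joint covariance of a belief
#'
#' @param belief a [joint_belief()].
#' @return The `(1 + D_q) x (1 + D_q)` covariance of `(z, w)`.
#' @export
joint_covariance <- function(belief) {
  rbind(c(belief$Sigma_zz, belief$Sigma_zw),
        cbind(belief$Sigma_zw, belief$Sigma_ww))
}

#' Default prior belief
#'
#' The prior used throughout the bundled experiments:
#' \eqn{\mu_z = 0}, \eqn{\Sigma_{zz} = 10^4} (covering the range of the
#' unknown signal), \eqn{\mu_w = 0}, \eqn{\Sigma_{ww} = I} (commands and
#' signal of the same order of magnitude), \eqn{\Sigma_{zw} = 0}.
#'
#' @param D_q command/weight dimension.
#' @return A [joint_belief()].
#' @export
piaf_priors <- function(D_q = 1) {
  joint_belief(mu_z = 0, mu_w = rep(0, D_q), Sigma_zz = 1e4,
               Sigma_ww = diag(D_q), Sigma_zw = rep(0, D_q))
}

#' @export
print.joint_belief <- function(x, ...) {
  cat("Joint belief over (z, w), D_q =", x$D_q, "\n")
  cat("  mu_z =", signif(x$mu_z, 5), " Sigma_zz =", signif(x$Sigma_zz, 5), "\n")
  cat("  mu_w =", paste(signif(x$mu_w, 5), collapse = ", "), "\n")
  cat("  diag(Sigma_ww) =", paste(signif(diag(x$Sigma_ww), 5), collapse = ", "),
      " Sigma_zw =", paste(signif(x$Sigma_zw, 5), collapse = ", "), "\n")
  invisible(x)
}
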