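#' Active non-negativity constraints of the baseline coefficients
#'
#' A spline coefficient is flagged as actively constrained when its value
#' is below `1e-2` and the corresponding gradient of the penalised
#' log-likelihood is below `-eps`: the optimum presses the coefficient
#' against the zero boundary. Ignoring active constraints when inverting
#' the information matrix can produce negative variances, so these
#' components are projected out of the covariance computation.
#'
#' @param theta fitted non-negative spline coefficients.
#' @param grad_theta gradient of the penalised log-likelihood with
#'   respect to `theta` at the fit.
#' @param eps positive gradient threshold (default `1e-2`).
#' @param value_tol value threshold below which a coefficient can be
#'   considered to sit on the boundary (default `1e-2`).
#' @return integer vector of active indices (possibly empty).
#' @export
detect_active <- function(theta, grad_theta, eps = 1e-2, value_tol = 1e-2) {
  stopifnot(length(theta) == length(grad_theta), eps > 0)
  which(theta < value_tol & grad_theta < -eps)
}

#' Constrained sandwich covariance of the penalised estimates
#'
#' Computes \eqn{\widehat{var}(\hat\eta) = A^{-1} G A^{-1}} where
#' \eqn{G} is the negative Hessian of the log-likelihood at the fit and
#' \eqn{A^{-1} = U[U'(G + 2\lambda R^*)U]^{-1}U'} restricts the penalised
#' information to the coefficients whose non-negativity constraint is not
#' active (\eqn{R^*} places the curvature penalty in the \eqn{\theta}
#' block). Rows and columns of actively constrained coefficients are
#' exactly zero.
#'
#' @param G negative Hessian of the unpenalised log-likelihood,
#'   dimension \eqn{(p+q+m)^2}.
#' @param Rmat the \eqn{m \times m} penalty matrix.
#' @param lambda the smoothing value at the fit.
#' @param active integer indices (within `theta`) of active constraints.
#' @param p,q numbers of time-fixed and time-varying covariates.
#' @param ridge relative ridge used if the reduced matrix is singular.
#' @return a symmetric \eqn{(p+q+m)^2} covariance matrix.
#' @export
sandwich_covariance <- function(G, Rmat, lambda, active, p, q,
                                ridge = 1e-8) {
  m <- nrow(Rmat)
  d <- p + q + m
  stopifnot(nrow(G) == d)
  M <- G
  idx_th <- p + q + seq_len(m)
  if (is.finite(lambda) && lambda > 0)
    M[idx_th, idx_th] <- M[idx_th, idx_th] + 2 * lambda * Rmat
  free <- setdiff(seq_len(d), p + q + active)
  Mr <- M[free, free, drop = FALSE]
  Mi <- tryCatch(solve(Mr), error = function(e) NULL)
  if (is.null(Mi)) {
    warning("penalised information is singular; adding a small ridge")
    lam <- ridge * max(sum(diag(Mr)) / nrow(Mr), 1) * 100
    Mi <- solve(Mr + diag(lam, nrow(Mr)))
  }
  Ainv <- matrix(0, d, d)
  Ainv[free, free] <- Mi
  V <- Ainv %*% G %*% Ainv
  V <- (V + t(V)) / 2
  dg <- diag(V)
  if (any(dg < -1e-8))
    stop("negative variance in the sandwich covariance; re-check the ",
         "active-constraint detection (an ignored active constraint is ",
         "the usual cause)")
  diag(V) <- pmax(dg, 0)
  V
}

#' Baseline hazard and survival estimates
#'
#' Evaluates the fitted baseline hazard \eqn{\hat h_0(t) = \sum_u
#' \hat\theta_u \psi_u(t)} and baseline survival \eqn{\hat S_0(t) =
#' \exp(-\sum_u \hat\theta_u \Psi_u(t))} with delta-method standard
#' errors propagated from the constrained sandwich covariance.
#'
#' @param fit an [mplcox()] object.
#' @param times evaluation times (clamped to the basis support).
#' @param level confidence level for the point-wise intervals.
#' @return a data frame with columns `time`, `estimate`, `se`, `lower`,
#'   `upper` (intervals truncated to `[0, 1]` for survival).
#' @export
baseline_survival <- function(fit, times, level = 0.95) {
  idx <- fit$p + fit$q + seq_len(fit$basis$m)
  Vth <- fit$vcov[idx, idx, drop = FALSE]
  Psi <- basis_Psi(fit$basis, times)
  H0 <- drop(Psi %*% fit$theta)
  S0 <- exp(-H0)
  # dS0/dtheta = -S0 * Psi
  varS <- S0^2 * rowSums((Psi %*% Vth) * Psi)
  se <- sqrt(pmax(varS, 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(time = times, estimate = S0, se = se,
             lower = pmax(S0 - zq * se, 0), upper = pmin(S0 + zq * se, 1))
}

#' @rdname baseline_survival
#' @export
baseline_hazard <- function(fit, times, level = 0.95) {
  idx <- fit$p + fit$q + seq_len(fit$basis$m)
  Vth <- fit$vcov[idx, idx, drop = FALSE]
  Ps <- basis_psi(fit$basis, times)
  h0 <- drop(Ps %*% fit$theta)
  se <- sqrt(pmax(rowSums((Ps %*% Vth) * Ps), 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(time = times, estimate = h0, se = se,
             lower = pmax(h0 - zq * se, 0), upper = h0 + zq * se)
}

#' Predicted survival curves with delta-method intervals
#'
#' Predicts the survival function for a covariate profile (a time-fixed
#' covariate vector plus a piecewise-constant time-varying trajectory)
#' with point-wise confidence intervals obtained by propagating the full
#' \eqn{(\beta,\gamma,\theta)} covariance through
#' \eqn{S(t) = \exp(-H(t))} via the delta method on the parameter scale.
#'
#' @param object an [mplcox()] fit.
#' @param x time-fixed covariate vector (length `p`); defaults to zeros
#'   (the baseline profile).
#' @param z_times change times of the time-varying covariates (first
#'   element must be 0); defaults to a single segment starting at 0.
#' @param z_values matrix with one row per element of `z_times` and `q`
#'   columns; defaults to zeros.
#' @param times evaluation time grid.
#' @param level confidence level.
#' @param ... unused.
#' @return a data frame with columns `time`, `surv`, `se`, `lower`,
#'   `upper`.
#' @export
predict.mplcox <- function(object, times, x = NULL, z_times = 0,
                           z_values = NULL, level = 0.95, ...) {
  p <- object$p; q <- object$q
  if (is.null(x)) x <- numeric(p)
  if (is.null(z_values)) z_values <- matrix(0, length(z_times), q)
  z_values <- matrix(z_values, nrow = length(z_times), ncol = q)
  if (z_times[1] != 0) stop("'z_times' must start at 0")
  tq <- .traj_quantities(object$basis, object$beta, object$gamma,
                         object$theta, x, z_times, z_values, times,
                         grad = TRUE)
  varH <- rowSums((tq$grad %*% object$vcov) * tq$grad)
  se <- tq$S * sqrt(pmax(varH, 0))
  zq <- stats::qnorm(1 - (1 - level) / 2)
  data.frame(time = times, surv = tq$S, se = se,
             lower = pmax(tq$S - zq * se, 0),
             upper = pmin(tq$S + zq * se, 1))
}
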