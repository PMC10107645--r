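#' Control parameters for the Newton-MI optimiser
#'
#' @param max_iter maximum number of inner (Newton/Newton/MI) iterations
#'   per smoothing value.
#' @param kkt_tol convergence tolerance on the Karush-Kuhn-Tucker
#'   residual: the sup-norm of the free-parameter gradient of the
#'   penalised log-likelihood, with positive gradients only counted for
#'   baseline coefficients at the zero boundary.
#' @param armijo_shrink,armijo_slope backtracking line-search constants
#'   (step shrink factor and sufficient-increase slope), both in (0, 1).
#' @param mi_eps small positive constant added to the
#'   multiplicative-iterative denominator to avoid division by zero.
#' @param ridge relative ridge added to a Newton block when it is
#'   numerically singular.
#' @param outer_max maximum number of smoothing-parameter updates.
#' @param nu_tol the smoothing loop stops once two consecutive values of
#'   the degrees-of-freedom quantity \eqn{\nu} differ by less than this.
#' @param lambda_init initial smoothing value for the outer loop.
#' @param active_eps gradient threshold \eqn{\varepsilon} of the
#'   active-constraint rule (`theta_u < 1e-2` and gradient `< -eps`).
#' @param theta_bnd baseline coefficients below this value are treated as
#'   being on the boundary when assessing the KKT conditions.
#' @param theta_sweeps number of multiplicative-iterative sweeps of the
#'   baseline coefficients per outer Newton cycle (the MI update has a
#'   linear convergence rate, the Newton blocks a quadratic one).
#' @param polish_enter KKT-residual level below which the optimiser
#'   switches to second-order refinement steps on the free coordinates
#'   (with the active non-negativity constraints held at the boundary)
#'   to certify the KKT conditions at full tolerance.
#' @return a list of class `mplcox_control`.
#' @export
mplcox_control <- function(max_iter = 5000L, kkt_tol = 1e-6,
                           armijo_shrink = 0.5, armijo_slope = 1e-2,
                           mi_eps = 1e-8, ridge = 1e-8,
                           outer_max = 20L, nu_tol = 1,
                           lambda_init = 1, active_eps = 1e-2,
                           theta_bnd = 1e-8, theta_sweeps = 5L,
                           polish_enter = 50) {
  stopifnot(max_iter >= 1, kkt_tol > 0,
            armijo_shrink > 0, armijo_shrink < 1,
            armijo_slope > 0, armijo_slope < 1,
            mi_eps > 0, ridge >= 0, outer_max >= 1, nu_tol > 0,
            lambda_init >= 0, active_eps > 0, theta_bnd > 0,
            theta_sweeps >= 1, polish_enter > 0)
  structure(list(max_iter = as.integer(max_iter), kkt_tol = kkt_tol,
                 armijo_shrink = armijo_shrink, armijo_slope = armijo_slope,
                 mi_eps = mi_eps, ridge = ridge,
                 outer_max = as.integer(outer_max), nu_tol = nu_tol,
                 lambda_init = lambda_init, active_eps = active_eps,
                 theta_bnd = theta_bnd,
                 theta_sweeps = as.integer(theta_sweeps),
                 polish_enter = polish_enter),
            class = "mplcox_control")
}

# Solve M x = g for a symmetric block M, adding a scaled ridge if the
# solve fails; preserves the ascent property of the Newton direction.
.ridge_solve <- function(M, g, ridge) {
  d <- nrow(M)
  tr <- sum(diag(M))
  lam <- ridge * max(tr / d, 1)
  for (k in 0:8) {
    Mk <- M + diag(lam * (10^k), d)
    x <- tryCatch(solve(Mk, g), error = function(e) NULL)
    if (!is.null(x) && all(is.finite(x))) return(x)
  }
  g / max(abs(diag(M)), 1)  # steepest-ascent fallback
}

# Backtracking Armijo line search for a maximisation step. When the
# predicted increase is below floating-point resolution of the objective,
# backtracking would compare rounding noise: in that regime the full
# (Newton or MI) step is taken directly — it lies in the local quadratic
# region where the update is contractive — and the reported objective
# stays monotone at reporting precision.
.armijo <- function(f, phi0, gd, control) {
  if (!is.finite(gd) || gd <= 0) return(list(w = 0, phi = phi0))
  if (gd < (abs(phi0) + 1) * 1e-9) {
    # accept the true objective value: tracking an inflated supremum here
    # would poison later line searches
    phi1 <- f(1)
    if (is.finite(phi1) && phi1 >= phi0 - (abs(phi0) + 1) * 1e-9)
      return(list(w = 1, phi = phi1))
  }
  w <- 1
  repeat {
    phi1 <- f(w)
    if (is.finite(phi1) && phi1 >= phi0 + control$armijo_slope * w * gd)
      return(list(w = w, phi = phi1))
    w <- w * control$armijo_shrink
    if (w < 1e-12) return(NULL)
  }
}

.kkt_residual <- function(gb, gg, gt, theta, bnd) {
  r <- 0
  if (length(gb)) r <- max(r, max(abs(gb)))
  if (length(gg)) r <- max(r, max(abs(gg)))
  if (length(gt)) {
    free <- theta > bnd
    if (any(free)) r <- max(r, max(abs(gt[free])))
    if (any(!free)) r <- max(r, max(pmax(gt[!free], 0)))
  }
  r
}

# Inner constrained maximisation of Phi at fixed lambda: alternating
# Newton step for beta, Newton step for gamma, multiplicative-iterative
# step for theta, each with an Armijo line search, until the KKT
# conditions hold. Phi is non-decreasing across accepted steps and theta
# stays non-negative throughout (multiplicative updates keep it positive).
.fit_inner <- function(cache, init, lambda, control, trace = FALSE) {
  beta <- init$beta; gamma <- init$gamma; theta <- init$theta
  p <- cache$p; q <- cache$q
  phi <- .ll_eval(cache, beta, gamma, theta, lambda)$phi
  if (!is.finite(phi))
    stop("initial parameter state gives a degenerate likelihood")
  phi_path <- numeric(control$max_iter)
  converged <- FALSE
  stalled_any <- FALSE
  iter <- 0L
  gb <- numeric(p); gg <- numeric(q); gt <- numeric(cache$m)

  skip_tol <- 0.5 * control$kkt_tol
  polish <- FALSE
  polish_fail <- 0L
  cooldown <- 0L
  for (k in seq_len(control$max_iter)) {
    iter <- k

    if (polish) {
      # Second-order refinement: once the alternating scheme has brought
      # the KKT residual down and the active set has settled, a Newton
      # step on the free coordinates (all of beta, gamma, and the theta
      # components away from the zero boundary or pushing into the
      # interior) reaches the tolerance in a few quadratic steps, which
      # the diagonally scaled MI update cannot do on correlated spline
      # coordinates.
      sc <- .ll_eval(cache, beta, gamma, theta, lambda, level = "hessian")
      gb <- sc$gb; gg <- sc$gg; gt <- sc$gt
      res <- .kkt_residual(gb, gg, gt, theta, control$theta_bnd)
      phi_path[k] <- phi
      if (res < control$kkt_tol) { converged <- TRUE; break }
      d <- p + q + cache$m
      Hphi <- sc$H
      thix <- p + q + seq_len(cache$m)
      if (lambda > 0)
        Hphi[thix, thix] <- Hphi[thix, thix] - 2 * lambda * cache$Rmat
      free_th <- theta > control$theta_bnd | gt > 0
      g <- c(gb, gg, gt)
      if (!all(is.finite(g)) || !all(is.finite(Hphi))) {
        # overflow in a derivative piece: retreat to the (guarded)
        # alternating scheme
        polish <- FALSE
        cooldown <- 5L
        next
      }
      # active-set restriction: components that the Newton direction
      # would push through the zero boundary from a near-zero value are
      # moved onto the boundary and the direction recomputed
      dir <- numeric(d)
      dropped <- rep(FALSE, cache$m)
      repeat {
        free <- c(rep(TRUE, p + q), free_th)
        dir[] <- 0
        dir[free] <- .ridge_solve(-Hphi[free, free, drop = FALSE], g[free],
                                  control$ridge)
        viol <- free_th & (theta + dir[thix] < 0) & theta < 1e-4
        if (!any(viol)) break
        dropped <- dropped | viol
        free_th <- free_th & !viol
        if (!any(free_th)) break
      }
      # coordinates pressed against the boundary ride the step onto it
      dir[thix][dropped & gt < 0] <- -theta[dropped & gt < 0]
      cap <- 50 * (1 + max(abs(c(beta, gamma, theta))))
      mx <- max(abs(dir))
      if (mx > cap) dir <- dir * (cap / mx)
      gd <- sum(g[free] * dir[free])
      stp <- NULL
      if (is.finite(gd) && gd > 0) {
        take <- function(w) {
          b2 <- beta + w * dir[seq_len(p)]
          g2 <- gamma + w * dir[p + seq_len(q)]
          t2 <- pmax(theta + w * dir[thix], 0)
          list(b = b2, g = g2, t = t2)
        }
        stp <- .armijo(function(w) {
          s <- take(w)
          .ll_eval(cache, s$b, s$g, s$t, lambda)$phi
        }, phi, gd, control)
      }
      if (is.null(stp)) {
        polish_fail <- polish_fail + 1L
        polish <- FALSE      # fall back to the alternating scheme
        cooldown <- 5L
        if (polish_fail > 25L) stalled_any <- TRUE
      } else {
        s <- take(stp$w)
        beta <- s$b; gamma <- s$g; theta <- s$t; phi <- stp$phi
        polish_fail <- 0L
      }
      next
    }
    # Step 1: Newton update of beta (skipped once its gradient already
    # meets the tolerance)
    if (p) {
      e <- .ll_eval(cache, beta, gamma, theta, lambda, level = "beta")
      gb <- e$gb
      if (max(abs(gb)) >= skip_tol) {
        dir <- .ridge_solve(-e$Hbb, gb, control$ridge)
        gd <- sum(gb * dir)
        if (is.finite(gd) && gd > 0) {
          st <- .armijo(function(w)
            .ll_eval(cache, beta + w * dir, gamma, theta, lambda)$phi,
            phi, gd, control)
          if (is.null(st)) stalled_any <- TRUE
          else { beta <- beta + st$w * dir; phi <- st$phi }
        }
      }
    }
    # Step 2: Newton update of gamma
    if (q) {
      e <- .ll_eval(cache, beta, gamma, theta, lambda, level = "gamma")
      gg <- e$gg
      if (max(abs(gg)) >= skip_tol) {
        dir <- .ridge_solve(-e$Hgg, gg, control$ridge)
        gd <- sum(gg * dir)
        if (is.finite(gd) && gd > 0) {
          st <- .armijo(function(w)
            .ll_eval(cache, beta, gamma + w * dir, theta, lambda)$phi,
            phi, gd, control)
          if (is.null(st)) stalled_any <- TRUE
          else { gamma <- gamma + st$w * dir; phi <- st$phi }
        }
      }
    }
    # Step 3: multiplicative-iterative update of theta. The diagonal
    # scaling S_uu = (B_u + eps)/theta_u (B = accumulated non-negative
    # "negative part" of the gradient) makes the unit step multiplicative:
    # theta <- theta * (A + eps)/(B + eps) >= 0. Several sweeps per
    # iteration: the MI step has a linear rate, the Newton blocks do not.
    for (sw in seq_len(control$theta_sweeps)) {
      e <- .ll_eval(cache, beta, gamma, theta, lambda, level = "mi")
      gt <- e$gt
      if (.kkt_residual(numeric(0), numeric(0), gt, theta,
                        control$theta_bnd) < skip_tol) break
      # components sitting on the zero boundary with a positive gradient
      # must be able to re-enter: give them an additive escape floor (the
      # purely multiplicative step cannot leave an exact zero)
      base <- pmax(theta, 1e-6 * (1 + max(theta)) * (gt > 0))
      step <- base * gt / (e$Bt + control$mi_eps)
      gd <- sum(gt * step)
      if (gd <= 0) break
      st <- .armijo(function(w)
        .ll_eval(cache, beta, gamma, pmax(theta + w * step, 0), lambda)$phi,
        phi, gd, control)
      if (is.null(st)) { stalled_any <- TRUE; break }
      theta <- pmax(theta + st$w * step, 0); phi <- st$phi
    }
    phi_path[k] <- phi

    # cheap residual from the per-step gradients; switch to the polish
    # phase once it is small, verify with a fresh full score before
    # declaring convergence
    res <- .kkt_residual(gb, gg, gt, theta, control$theta_bnd)
    if (cooldown > 0L) cooldown <- cooldown - 1L
    if (res < control$polish_enter * max(1, cache$n / 100) &&
        polish_fail <= 25L && cooldown == 0L)
      polish <- TRUE
    if (res < control$kkt_tol) {
      sc <- .ll_eval(cache, beta, gamma, theta, lambda, level = "score")
      res2 <- .kkt_residual(sc$gb, sc$gg, sc$gt, theta, control$theta_bnd)
      if (res2 < control$kkt_tol) { converged <- TRUE; break }
    }
  }
  sc <- .ll_eval(cache, beta, gamma, theta, lambda, level = "score")
  list(beta = beta, gamma = gamma, theta = theta, phi = phi,
       loglik = sc$ll,
       iterations = iter, converged = converged, stalled = stalled_any,
       kkt_residual = .kkt_residual(sc$gb, sc$gg, sc$gt, theta,
                                    control$theta_bnd),
       score = sc, phi_path = phi_path[seq_len(iter)])
}

# One marginal-likelihood smoothing update:
# sigma2_new = theta'R theta / (m - nu), nu = tr((G + Q)^{-1} Q),
# Q = blockdiag(0, 0, R/sigma2), G = -Hessian of the log-likelihood.
.update_sigma2 <- function(G, Rmat, theta, sigma2, p, q, ridge = 1e-8) {
  m <- length(theta)
  d <- p + q + m
  Q <- matrix(0, d, d)
  idx <- p + q + seq_len(m)
  Q[idx, idx] <- Rmat / sigma2
  GQ <- G + Q
  sol <- tryCatch(solve(GQ, Q), error = function(e) NULL)
  if (is.null(sol)) {
    lam <- ridge * max(sum(diag(GQ)) / d, 1)
    sol <- solve(GQ + diag(lam * 100, d), Q)
  }
  nu <- sum(diag(sol))
  thRth <- drop(theta %*% Rmat %*% theta)
  if (thRth < 1e-12)
    return(list(sigma2 = sigma2, nu = nu, flat = TRUE))
  if (m - nu <= 0)
    stop("numerical degeneracy in smoothing update: m - nu <= 0")
  list(sigma2 = thRth / (m - nu), nu = nu, flat = FALSE)
}

# Laplace-approximated log-marginal likelihood of sigma2 (diagnostic).
.marginal_loglik <- function(ll, theta, Rmat, G, sigma2, p, q) {
  m <- length(theta)
  d <- p + q + m
  Q <- matrix(0, d, d)
  idx <- p + q + seq_len(m)
  Q[idx, idx] <- Rmat / sigma2
  GQ <- G + Q
  ch <- tryCatch(chol(GQ), error = function(e) NULL)
  logdet <- if (!is.null(ch)) 2 * sum(log(diag(ch))) else {
    ev <- eigen(GQ, symmetric = TRUE, only.values = TRUE)$values
    ev <- ev[ev > 1e-12]
    if (!length(ev)) stop("degenerate determinant in marginal likelihood")
    warning("G + Q not positive definite; using pseudo-determinant")
    sum(log(ev))
  }
  -(m / 2) * log(sigma2) + ll -
    drop(theta %*% Rmat %*% theta) / (2 * sigma2) - logdet / 2
}

#' Fit an extended Cox model by maximum penalised likelihood
#'
#' Maximises the penalised log-likelihood
#' \eqn{\Phi(\eta) = \ell(\beta,\gamma,\theta) - \lambda\,\theta'R\theta}
#' over the regression coefficients and the non-negative M-spline
#' coefficients of the baseline hazard, for partly interval-censored data
#' with piecewise-constant time-varying covariates. Optimisation
#' alternates a Newton step for \eqn{\beta}, a Newton step for
#' \eqn{\gamma} and a multiplicative-iterative step for \eqn{\theta}
#' (which preserves non-negativity), each with an Armijo line search, so
#' the objective never decreases.
#'
#' When `lambda` is `NULL` (the default) the smoothing parameter is chosen
#' automatically: the penalty is read as a normal prior
#' \eqn{\theta \sim N(0, \sigma^2 R^{-1})} with \eqn{\sigma^2 =
#' 1/(2\lambda)}, and inner fits alternate with the marginal-likelihood
#' update \eqn{\sigma^2 = \hat\theta'R\hat\theta/(m-\nu)},
#' \eqn{\nu = \mathrm{tr}\{(G+Q)^{-1}Q\}}, until \eqn{\nu} stabilises
#' (consecutive change below 1).
#'
#' Inference uses the constrained sandwich covariance: coefficients with
#' an active non-negativity constraint (small value, negative gradient)
#' are projected out before inverting the penalised information, and the
#' covariance of the remaining block is
#' \eqn{A^{-1}(-\partial^2\ell)A^{-1}}.
#'
#' @param data a [tvc_data()] object.
#' @param m optional basis dimension override (total number of spline
#'   functions); by default the cube-root rule on the number of
#'   non-right-censored subjects.
#' @param lambda fixed smoothing value; `NULL` (default) selects it
#'   automatically by marginal likelihood.
#' @param basis optional pre-built [mspline_basis()].
#' @param control an [mplcox_control()] list.
#' @return an object of class `mplcox` with components including
#'   `beta`, `gamma`, `theta`, `vcov`, `active` (indices of actively
#'   constrained spline coefficients), `lambda`, `sigma2`, `nu`, `basis`,
#'   and convergence diagnostics.
#' @examples
#' cfg <- sim_preset("s2s1-weibull", n = 120, seed = 7)
#' dat <- simulate_tvc(cfg)
#' fit <- mplcox(dat)
#' summary(fit)
#' @export
mplcox <- function(data, m = NULL, lambda = NULL, basis = NULL,
                   control = mplcox_control()) {
  stopifnot(inherits(data, "tvc_data"))
  sub <- data$subjects
  n0 <- sum(sub$censor_type != "right")
  if (n0 == 0)
    stop("all subjects are right-censored: no information about the ",
         "baseline hazard scale")
  if (is.null(basis)) {
    times <- c(sub$yL[sub$yL > 0], sub$yR[is.finite(sub$yR)])
    basis <- mspline_basis(times, n0 = n0, m = m)
  }
  cache <- .ll_cache(data, basis)
  p <- cache$p; q <- cache$q; mb <- basis$m

  # scale-aware start: constant theta such that H0 at the median finite
  # time matches the crude cumulative hazard of the non-right-censored
  # fraction
  t_med <- stats::median(sub$y)
  frac <- min(n0 / data$n, 0.95)
  target <- max(-log(1 - frac), 0.05)
  cpsi <- sum(basis_Psi(basis, t_med))
  init <- list(beta = numeric(p), gamma = numeric(q),
               theta = rep(target / max(cpsi, 1e-12), mb))

  smooth <- is.null(lambda)
  history <- list()
  if (!smooth) {
    stopifnot(lambda >= 0)
    fit <- .fit_inner(cache, init, lambda, control)
    sigma2 <- if (lambda > 0) 1 / (2 * lambda) else Inf
    hess <- .ll_eval(cache, fit$beta, fit$gamma, fit$theta, lambda,
                     level = "hessian")
    G <- -hess$H
    nu <- NA_real_
    outer_iter <- 1L
    flat <- FALSE
  } else {
    lambda <- control$lambda_init
    sigma2 <- if (lambda > 0) 1 / (2 * lambda) else Inf
    nu <- NA_real_
    cur <- init
    flat <- FALSE
    capped <- FALSE
    ls_hist <- numeric(0)
    outer_iter <- 0L
    # intermediate fits only steer the smoothing update; they run at a
    # loose tolerance, and a final full-tolerance fit follows below
    ctl_loose <- control
    ctl_loose$kkt_tol <- max(control$kkt_tol, 1e-3)
    # intermediate fits are inexact: they only steer the smoothing update
    ctl_loose$max_iter <- min(control$max_iter, 60L)
    repeat {
      outer_iter <- outer_iter + 1L
      fit <- .fit_inner(cache, cur, lambda, ctl_loose)
      cur <- list(beta = fit$beta, gamma = fit$gamma, theta = fit$theta)
      hess <- .ll_eval(cache, fit$beta, fit$gamma, fit$theta, lambda,
                       level = "hessian")
      G <- -hess$H
      up <- tryCatch(.update_sigma2(G, basis$R, fit$theta, sigma2, p, q),
                     error = function(e) NULL)
      if (is.null(up)) {
        # indefinite curvature at the boundary can push nu past m; keep
        # the current smoothing value and stop updating it
        warning("smoothing update degenerate (m - nu <= 0); ",
                "keeping lambda = ", format(lambda, digits = 4))
        break
      }
      history[[outer_iter]] <- c(sigma2 = sigma2, lambda = lambda,
                                 nu = up$nu, phi = fit$phi)
      if (up$flat) { flat <- TRUE; nu <- up$nu; break }
      # nu alone moves little when m is small, so the nu-stabilisation
      # rule is paired with stabilisation of sigma2 itself
      if (!is.na(nu) && abs(up$nu - nu) < control$nu_tol &&
          abs(up$sigma2 - sigma2) < 0.02 * sigma2) {
        nu <- up$nu
        break
      }
      nu <- up$nu
      # the sandwich theory assumes lambda << n; when the data prefer an
      # effectively straight-line baseline the marginal-likelihood update
      # diverges (theta'R theta -> 0), so lambda is capped at n/2 and the
      # loop stops there
      if (1 / (2 * up$sigma2) > data$n / 2) {
        lambda <- data$n / 2
        sigma2 <- 1 / (2 * lambda)
        capped <- TRUE
        fit <- .fit_inner(cache, cur, lambda, ctl_loose)
        cur <- list(beta = fit$beta, gamma = fit$gamma, theta = fit$theta)
        hess <- .ll_eval(cache, fit$beta, fit$gamma, fit$theta, lambda,
                         level = "hessian")
        G <- -hess$H
        break
      }
      ls_hist <- c(ls_hist, log(up$sigma2))
      sigma2 <- up$sigma2
      # Aitken extrapolation of the linearly convergent log(sigma2)
      # fixed-point sequence
      nh <- length(ls_hist)
      if (nh >= 3L && nh %% 3L == 0L) {
        d1 <- ls_hist[nh - 1] - ls_hist[nh - 2]
        d2 <- ls_hist[nh] - ls_hist[nh - 1]
        r <- if (abs(d1) > 1e-12) d2 / d1 else 0
        if (is.finite(r) && r > 0 && r < 0.95)
          sigma2 <- exp(ls_hist[nh] + d2 * r / (1 - r))
      }
      sigma2 <- max(sigma2, 1 / data$n)  # lambda cap binds here too
      lambda <- 1 / (2 * sigma2)
      if (outer_iter >= control$outer_max) break
    }
    fit <- .fit_inner(cache, cur, lambda, control)
    hess <- .ll_eval(cache, fit$beta, fit$gamma, fit$theta, lambda,
                     level = "hessian")
    G <- -hess$H
  }

  if (!exists("capped", inherits = FALSE)) capped <- FALSE
  if (!capped && is.finite(lambda) && lambda / data$n >= 1)
    warning("selected smoothing parameter is large relative to n ",
            "(lambda/n >= 1); asymptotic approximations may be poor")

  active <- detect_active(fit$theta, fit$score$gt, eps = control$active_eps)
  V <- sandwich_covariance(G, basis$R, lambda, active, p, q,
                           ridge = control$ridge)
  cn <- c(data$x_cols, data$z_cols)
  coefs <- c(fit$beta, fit$gamma)
  names(coefs) <- cn
  dimnames(V) <- rep(list(c(cn, paste0("theta", seq_len(mb)))), 2)

  structure(list(
    coefficients = coefs, beta = fit$beta, gamma = fit$gamma,
    theta = fit$theta, basis = basis, lambda = lambda, sigma2 = sigma2,
    nu = nu, vcov = V, active = active,
    loglik = fit$loglik, phi = fit$phi,
    converged = fit$converged, iterations = fit$iterations,
    lambda_capped = capped,
    outer_iterations = outer_iter, kkt_residual = fit$kkt_residual,
    score = fit$score, G = G, flat_penalty = flat,
    smoothing_history = history, phi_path = fit$phi_path,
    n = data$n, n0 = n0, p = p, q = q,
    x_cols = data$x_cols, z_cols = data$z_cols,
    control = control, data = data),
    class = "mplcox")
}

#' @export
print.mplcox <- function(x, ...) {
  cat("Extended Cox model fitted by maximum penalised likelihood\n")
  cat("  n = ", x$n, " (", x$n0, " non-right-censored), m = ", x$basis$m,
      " spline functions\n", sep = "")
  cat("  lambda = ", format(x$lambda, digits = 4),
      ", nu = ", format(x$nu, digits = 4),
      ", penalised loglik = ", format(x$phi, digits = 6), "\n", sep = "")
  if (length(x$coefficients)) {
    cat("Coefficients:\n")
    print(x$coefficients)
  }
  if (!x$converged)
    cat("Warning: inner optimisation did not meet the KKT tolerance ",
        "(residual ", format(x$kkt_residual, digits = 3), ")\n", sep = "")
  invisible(x)
}

#' @export
coef.mplcox <- function(object, ...) object$coefficients

#' @export
vcov.mplcox <- function(object, ...) {
  idx <- seq_len(object$p + object$q)
  object$vcov[idx, idx, drop = FALSE]
}

#' @export
logLik.mplcox <- function(object, ...) {
  structure(object$loglik, df = object$p + object$q + object$basis$m -
              length(object$active), class = "logLik")
}

#' @export
summary.mplcox <- function(object, ...) {
  est <- object$coefficients
  se <- sqrt(pmax(diag(object$vcov)[seq_along(est)], 0))
  z <- est / se
  ptab <- data.frame(Estimate = est, SE = se, z = z,
                     `p-value` = 2 * stats::pnorm(-abs(z)),
                     check.names = FALSE, row.names = names(est))
  out <- list(coefficients = ptab, lambda = object$lambda, nu = object$nu,
              n = object$n, n0 = object$n0, m = object$basis$m,
              active = object$active, converged = object$converged,
              loglik = object$loglik)
  class(out) <- "summary.mplcox"
  out
}

#' @export
print.summary.mplcox <- function(x, ...) {
  cat("Extended Cox model (maximum penalised likelihood)\n")
  cat("n =", x$n, "; non-right-censored =", x$n0, "; spline functions =",
      x$m, "\n")
  cat("lambda =", format(x$lambda, digits = 4),
      "; nu =", format(x$nu, digits = 4),
      "; loglik =", format(x$loglik, digits = 6), "\n\n")
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  if (length(x$active))
    cat("\nActively constrained baseline coefficients:",
        paste(x$active, collapse = ", "), "\n")
  invisible(x)
}
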