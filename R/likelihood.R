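# Penalised log-likelihood of the extended Cox model under partly
# interval censoring, with analytic first and second derivatives.
#
# For subject i with piecewise-constant time-varying covariates z_i(t)
# (value z_ia on [t_ia, t_{i,a+1})), the model hazard is
#   h_i(t) = h0(t) exp(x_i'beta + z_i(t)'gamma),   h0(t) = sum_u theta_u psi_u(t),
# and the cumulative hazard telescopes over the covariate segments:
#   H_i(t) = exp(x_i'beta) * sum_u theta_u Psi*_ui(t),
#   Psi*_ui(t) = sum_a [Psi_u(t ^ t_{i,a+1}) - Psi_u(t ^ t_ia)] exp(z_ia'gamma).
# The log-likelihood adds, per subject,
#   event:    log h0(y) + x'beta + z(y)'gamma - H(y)
#   right:    -H(yL)
#   left:     log(1 - S(yR))
#   interval: log(S(yL) - S(yR)),     S = exp(-H).
# All derivatives below follow by the chain rule through H at the (at most
# two) relevant evaluation times per subject; left/interval contributions
# add rank-one terms in the gradient vector of H.

# Per-dataset, per-basis precomputation. The clipped cumulative-basis
# increments depend only on observed times, never on parameters, so they
# are computed once: dPsi1/dPsi2 hold, per covariate segment j of subject
# i(j), the increment Psi_u(min(T, tstop_j)) - Psi_u(min(T, tstart_j)) for
# the subject's lower (T1) and upper (T2) likelihood evaluation times.
.ll_cache <- function(data, basis) {
  sub <- data$subjects
  ty <- sub$censor_type
  ev <- ty == "event"; ri <- ty == "right"
  le <- ty == "left";  it <- ty == "interval"
  n <- data$n; m <- basis$m
  T1 <- ifelse(ev, sub$y, ifelse(ri | it, sub$yL, 0))
  T2 <- ifelse(le | it, sub$yR, 0)

  sid <- data$sid
  clip_incr <- function(Tn) {
    Ts <- Tn[sid]
    basis_Psi(basis, pmin(Ts, data$tstop)) -
      basis_Psi(basis, pmin(Ts, data$tstart))
  }
  dPsi1 <- clip_incr(T1)
  dPsi2 <- clip_incr(T2)

  psiE <- matrix(0, n, m)
  zE <- matrix(0, n, data$q)
  if (any(ev)) {
    psiE[ev, ] <- basis_psi(basis, sub$y[ev])
    for (i in which(ev)) {
      rows <- which(sid == i)
      a <- max(findInterval(sub$y[i], data$tstart[rows]), 1L)
      zE[i, ] <- data$Z[rows[a], ]
    }
  }

  list(n = n, p = data$p, q = data$q, m = m, N = data$N,
       X = data$X, Z = data$Z, sid = sid,
       ends = cumsum(tabulate(sid, n)),
       ev = ev, ri = ri, le = le, it = it, delta = as.numeric(ev),
       dPsi1 = dPsi1, dPsi2 = dPsi2, psiE = psiE, zE = zE,
       Rmat = basis$R)
}

# Group sums over contiguous subject blocks (rows sorted by subject):
# cumulative sums sampled at the block ends, differenced. Equivalent to
# rowsum() but without its per-call grouping overhead.
.grp_sum <- function(M, ends) {
  if (is.null(dim(M))) {
    cs <- cumsum(M)[ends]
    return(cs - c(0, cs[-length(cs)]))
  }
  out <- matrix(0, length(ends), ncol(M))
  for (j in seq_len(ncol(M))) {
    cs <- cumsum(M[, j])[ends]
    out[, j] <- cs - c(0, cs[-length(cs)])
  }
  out
}

# Evaluate the penalised log-likelihood and (optionally) derivatives.
# level: "ll" (objective only), "beta"/"gamma" (score + curvature block for
# one Newton step), "mi" (theta gradient split into non-negative parts for
# the multiplicative-iterative step), "score" (full gradient), "hessian"
# (full (p+q+m)^2 Hessian of the unpenalised log-likelihood, plus score).
.ll_eval <- function(cache, beta, gamma, theta, lambda, level = "ll") {
  X <- cache$X; Z <- cache$Z; sid <- cache$sid
  p <- cache$p; q <- cache$q; m <- cache$m
  Rmat <- cache$Rmat
  ev <- cache$ev; ri <- cache$ri; le <- cache$le; it <- cache$it

  etax <- if (p) drop(X %*% beta) else numeric(cache$n)
  emu <- exp(etax)
  wseg <- if (q) drop(exp(Z %*% gamma)) else rep(1, cache$N)
  H01seg <- drop(cache$dPsi1 %*% theta)
  H02seg <- drop(cache$dPsi2 %*% theta)
  H1 <- emu * .grp_sum(wseg * H01seg, cache$ends)
  H2 <- emu * .grp_sum(wseg * H02seg, cache$ends)
  S1 <- exp(-H1); S2 <- exp(-H2)
  h0E <- drop(cache$psiE %*% theta)

  tiny <- 1e-300
  floored <- FALSE
  ll <- 0
  if (any(ev)) {
    if (any(h0E[ev] <= 0) || any(!is.finite(h0E[ev]))) {
      ll <- -Inf
    } else {
      zEg <- if (q) drop(cache$zE %*% gamma) else numeric(cache$n)
      ll <- ll + sum(log(h0E[ev]) + etax[ev] + zEg[ev] - H1[ev])
    }
  }
  if (is.finite(ll)) {
    if (any(ri)) ll <- ll - sum(H1[ri])
    one_mS2 <- -expm1(-H2)
    if (any(le)) {
      v <- one_mS2[le]
      if (any(v < tiny)) floored <- TRUE
      ll <- ll + sum(log(pmax(v, tiny)))
    }
    Dit <- S1 - S2
    if (any(it)) {
      v <- Dit[it]
      if (any(v < tiny)) floored <- TRUE
      ll <- ll + sum(log(pmax(v, tiny)))
    }
  }
  pen <- lambda * drop(theta %*% Rmat %*% theta)
  out <- list(ll = ll, phi = ll - pen, floored = floored,
              H1 = H1, H2 = H2)
  if (level == "ll" || !is.finite(ll)) return(out)

  # per-subject chain-rule coefficients: contributions c1*dH(T1) + c2*dH(T2)
  # to the score, with the same c's multiplying the Hessian of H, and
  # rank-one coefficients k11, k22, k12 on grad(H) outer products.
  nsub <- cache$n
  c1 <- numeric(nsub); c2 <- numeric(nsub)
  k11 <- numeric(nsub); k22 <- numeric(nsub); k12 <- numeric(nsub)
  c1[ev | ri] <- -1
  if (any(le)) {
    v <- pmax(-expm1(-H2[le]), tiny)
    w <- S2[le] / v
    k <- -S2[le] / v^2
    # a left-censored interval ending at (or before) the basis boundary
    # has H(yR) = 0 identically: the subject carries no derivative
    # information and its coefficients would overflow
    dead <- H2[le] <= 0
    w[dead] <- 0; k[dead] <- 0
    c2[le] <- w
    k22[le] <- k
  }
  if (any(it)) {
    D <- pmax(S1[it] - S2[it], tiny)
    r1 <- S1[it] / D; r2 <- S2[it] / D
    dead <- H1[it] >= H2[it]   # degenerate interval: no mass between
    r1[dead] <- 0; r2[dead] <- 0
    c1[it] <- -r1
    c2[it] <- r2
    k11[it] <- r1 - r1^2
    k22[it] <- -r2 - r2^2
    k12[it] <- r1 * r2
  }

  pen_g <- 2 * lambda * drop(Rmat %*% theta)

  if (level == "beta") {
    gb <- drop(crossprod(X, cache$delta + c1 * H1 + c2 * H2))
    wbb <- c1 * H1 + c2 * H2 + k11 * H1^2 + k22 * H2^2 + 2 * k12 * H1 * H2
    out$gb <- gb
    out$Hbb <- crossprod(X, X * wbb)
    return(out)
  }

  # n x q per-subject gradient of H wrt gamma (already includes exp(x'beta))
  if (level %in% c("gamma", "score", "hessian")) {
    A1 <- emu * .grp_sum(Z * (wseg * H01seg), cache$ends)
    A2 <- emu * .grp_sum(Z * (wseg * H02seg), cache$ends)
  }

  if (level == "gamma") {
    gg <- drop(crossprod(cache$zE, cache$delta)) + colSums(A1 * c1 + A2 * c2)
    c1s <- c1[sid]; c2s <- c2[sid]; emus <- emu[sid]
    useg <- wseg * emus * (c1s * H01seg + c2s * H02seg)
    Hgg <- crossprod(Z, Z * useg) +
      crossprod(A1, A1 * k11) + crossprod(A2, A2 * k22) +
      crossprod(A1, A2 * k12) + crossprod(A2, A1 * k12)
    out$gg <- gg
    out$Hgg <- Hgg
    return(out)
  }

  # n x m matrices e^{x'beta} Psi*_u(T) and event term psi_u(y)/h0(y)
  Psi1m <- emu * .grp_sum(cache$dPsi1 * wseg, cache$ends)
  Psi2m <- emu * .grp_sum(cache$dPsi2 * wseg, cache$ends)
  psiEh <- cache$psiE / pmax(h0E, tiny)

  gt_pos <- colSums(psiEh) + colSums(Psi2m * c2)
  gt_neg <- colSums(Psi1m * (-c1))
  At <- gt_pos + pmax(-pen_g, 0)
  Bt <- gt_neg + pmax(pen_g, 0)
  out$At <- At; out$Bt <- Bt
  out$gt <- At - Bt
  if (level == "mi") return(out)

  out$gb <- drop(crossprod(X, cache$delta + c1 * H1 + c2 * H2))
  out$gg <- drop(crossprod(cache$zE, cache$delta)) + colSums(A1 * c1 + A2 * c2)
  if (level == "score") return(out)

  # full Hessian of the unpenalised log-likelihood
  c1s <- c1[sid]; c2s <- c2[sid]; emus <- emu[sid]
  wbb <- c1 * H1 + c2 * H2
  Hbb <- crossprod(X, X * wbb)
  Hbg <- crossprod(X, A1 * c1 + A2 * c2)
  Hbt <- crossprod(X, Psi1m * c1 + Psi2m * c2)
  useg <- wseg * emus * (c1s * H01seg + c2s * H02seg)
  Hgg <- crossprod(Z, Z * useg)
  Hgt <- crossprod(Z * (wseg * emus * c1s), cache$dPsi1) +
         crossprod(Z * (wseg * emus * c2s), cache$dPsi2)
  Htt <- -crossprod(psiEh * sqrt(cache$delta))

  Hl <- matrix(0, p + q + m, p + q + m)
  ib <- seq_len(p); ig <- p + seq_len(q); itx <- p + q + seq_len(m)
  Hl[ib, ib] <- Hbb; Hl[ib, ig] <- Hbg; Hl[ib, itx] <- Hbt
  Hl[ig, ig] <- Hgg; Hl[ig, itx] <- Hgt
  Hl[itx, itx] <- Htt
  Hl[lower.tri(Hl)] <- t(Hl)[lower.tri(Hl)]

  # rank-one terms from the left/interval log-difference contributions
  D1 <- cbind(X * H1, A1, Psi1m)
  D2 <- cbind(X * H2, A2, Psi2m)
  M12 <- crossprod(D1, D2 * k12)
  Hl <- Hl + crossprod(D1, D1 * k11) + crossprod(D2, D2 * k22) + M12 + t(M12)
  Hl <- (Hl + t(Hl)) / 2

  out$H <- Hl
  # diagnostic weights: for event/right-only data the Hessian weight A and
  # the score residual weight C coincide
  out$wA <- -(wbb + k11 * H1^2 + k22 * H2^2 + 2 * k12 * H1 * H2)
  out$wC <- -(c1 * H1 + c2 * H2)
  out
}

#' Log-likelihood of the extended Cox model
#'
#' Evaluates the partly interval-censored log-likelihood (and its
#' penalised counterpart) at given parameter values. Mostly useful for
#' diagnostics; fitting is done by [mplcox()].
#'
#' @param data a [tvc_data()] object.
#' @param basis an [mspline_basis()] object.
#' @param beta,gamma,theta parameter vectors (all `theta` entries must be
#'   non-negative).
#' @param lambda smoothing parameter \eqn{\lambda \ge 0} multiplying the
#'   curvature penalty \eqn{\theta' R \theta} in `penalised_loglik()`.
#' @return a single numeric value.
#' @export
log_likelihood <- function(data, basis, beta, gamma, theta) {
  stopifnot(all(theta >= 0))
  cache <- .ll_cache(data, basis)
  ll <- .ll_eval(cache, beta, gamma, theta, lambda = 0)$ll
  if (!is.finite(ll))
    stop("likelihood-degenerate: h0 vanishes at an observed event time")
  ll
}

#' @rdname log_likelihood
#' @export
penalised_loglik <- function(data, basis, beta, gamma, theta, lambda) {
  stopifnot(all(theta >= 0), lambda >= 0)
  cache <- .ll_cache(data, basis)
  phi <- .ll_eval(cache, beta, gamma, theta, lambda)$phi
  if (!is.finite(phi))
    stop("likelihood-degenerate: h0 vanishes at an observed event time")
  phi
}

# ---- trajectory-level quantities (shared by prediction and simulation) ----

# Psi*_u(t) for one covariate trajectory: z_starts[1] must be 0, Zmat has
# one row per segment; the last value is carried forward beyond the final
# change time. Returns a length(t) x m matrix.
.traj_psi_star <- function(basis, gamma, z_starts, Zmat, t) {
  K <- length(z_starts)
  f <- if (ncol(Zmat)) drop(exp(Zmat %*% gamma)) else rep(1, K)
  ends <- c(z_starts[-1], Inf)
  out <- matrix(0, length(t), basis$m)
  for (a in seq_len(K)) {
    lo <- pmin(t, z_starts[a]); hi <- pmin(t, ends[a])
    out <- out + f[a] * (basis_Psi(basis, hi) - basis_Psi(basis, lo))
  }
  out
}

# Hazard/cumulative hazard/survival (and optionally the gradient of H in
# eta = (beta, gamma, theta)) along one covariate trajectory.
.traj_quantities <- function(basis, beta, gamma, theta, x, z_starts, Zmat,
                             t, grad = FALSE) {
  p <- length(beta); q <- length(gamma)
  emu <- exp(if (p) sum(x * beta) else 0)
  Pst <- .traj_psi_star(basis, gamma, z_starts, Zmat, t)
  H0s <- drop(Pst %*% theta)
  H <- emu * H0s
  a_idx <- pmax(findInterval(t, z_starts), 1L)
  zt <- Zmat[a_idx, , drop = FALSE]
  h <- drop(basis_psi(basis, t) %*% theta) * emu *
    (if (q) drop(exp(zt %*% gamma)) else 1)
  out <- list(H = H, h = h, S = exp(-H))
  if (grad) {
    K <- length(z_starts)
    f <- if (q) drop(exp(Zmat %*% gamma)) else rep(1, K)
    ends <- c(z_starts[-1], Inf)
    dg <- matrix(0, length(t), q)
    for (a in seq_len(K)) {
      lo <- pmin(t, z_starts[a]); hi <- pmin(t, ends[a])
      dH0a <- drop((basis_Psi(basis, hi) - basis_Psi(basis, lo)) %*% theta)
      if (q) dg <- dg + outer(f[a] * dH0a, Zmat[a, ])
    }
    out$grad <- cbind(
      if (p) outer(H, x) else matrix(0, length(t), 0),
      emu * dg,
      emu * Pst)
  }
  out
}
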