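# Independent oracles used across the test files.

# Textbook M-spline recursion, written directly from the definition:
#   M_{i,1}(x) = 1/(t_{i+1}-t_i)               on [t_i, t_{i+1})
#   M_{i,k}(x) = k [ (x-t_i) M_{i,k-1}(x) + (t_{i+k}-x) M_{i+1,k-1}(x) ]
#                / ((k-1)(t_{i+k}-t_i))
# evaluated term by term on the augmented knot sequence (boundary knots
# repeated `order` times). Each M_{i,k} integrates to one. Intended for
# interior evaluation points.
mspline_recursion <- function(knots, order, x) {
  nb <- length(knots) - order
  M1 <- function(i, x) {
    d <- knots[i + 1] - knots[i]
    if (d <= 0) return(rep(0, length(x)))
    as.numeric(x >= knots[i] & x < knots[i + 1]) / d
  }
  Mk <- function(i, k, x) {
    if (k == 1) return(M1(i, x))
    d <- knots[i + k] - knots[i]
    if (d <= 0) return(rep(0, length(x)))
    k * ((x - knots[i]) * Mk(i, k - 1, x) +
           (knots[i + k] - x) * Mk(i + 1, k - 1, x)) / ((k - 1) * d)
  }
  vapply(seq_len(nb), function(i) Mk(i, order, x), numeric(length(x)))
}

# central-difference gradient
num_grad <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    e <- numeric(length(x)); e[i] <- h
    (f(x + e) - f(x - e)) / (2 * h)
  }, numeric(1))
}

# central-difference Hessian of a scalar function via its gradient
num_hess_from_grad <- function(gfun, x, h = 1e-6) {
  d <- length(x)
  H <- matrix(0, d, d)
  for (i in seq_len(d)) {
    e <- numeric(d); e[i] <- h
    H[i, ] <- (gfun(x + e) - gfun(x - e)) / (2 * h)
  }
  (H + t(H)) / 2
}

# small hand-built dataset containing all four censoring types, two
# time-fixed and one time-varying covariate
make_mixed_data <- function() {
  df <- rbind(
    data.frame(id = 1, tstart = 0,   tstop = 1.2, yL = 1.2, yR = 1.2,
               censor_type = "event",    x1 = 1, x2 = 0.3, z1 = 0),
    data.frame(id = 2, tstart = 0,   tstop = 0.8, yL = 2.0, yR = 2.0,
               censor_type = "event",    x1 = 0, x2 = 0.7, z1 = 0),
    data.frame(id = 2, tstart = 0.8, tstop = 2.0, yL = 2.0, yR = 2.0,
               censor_type = "event",    x1 = 0, x2 = 0.7, z1 = 1),
    data.frame(id = 3, tstart = 0,   tstop = 1.5, yL = 1.5, yR = Inf,
               censor_type = "right",    x1 = 1, x2 = 0.9, z1 = 0),
    data.frame(id = 4, tstart = 0,   tstop = 0.4, yL = 0,   yR = 0.9,
               censor_type = "left",     x1 = 0, x2 = 0.2, z1 = 0),
    data.frame(id = 4, tstart = 0.4, tstop = 0.9, yL = 0,   yR = 0.9,
               censor_type = "left",     x1 = 0, x2 = 0.2, z1 = 1),
    data.frame(id = 5, tstart = 0,   tstop = 0.6, yL = 0.7, yR = 1.8,
               censor_type = "interval", x1 = 1, x2 = 0.5, z1 = 0),
    data.frame(id = 5, tstart = 0.6, tstop = 1.8, yL = 0.7, yR = 1.8,
               censor_type = "interval", x1 = 1, x2 = 0.5, z1 = 1),
    data.frame(id = 6, tstart = 0,   tstop = 2.4, yL = 2.4, yR = Inf,
               censor_type = "right",    x1 = 0, x2 = 0.1, z1 = 0))
  tvc_data(df)
}

mixed_basis <- function(dat, m = NULL) {
  sub <- dat$subjects
  mspline_basis(c(sub$yL[sub$yL > 0], sub$yR[is.finite(sub$yR)]),
                n0 = sum(sub$censor_type != "right"), m = m)
}

# numerically integrated cumulative hazard along a piecewise-constant
# covariate trajectory (independent of the analytic Psi* path). The
# baseline hazard carries no mass outside the basis support, and the
# integrand jumps at covariate change times, so the quadrature runs
# piecewise from basis$a and splits at the change points.
quad_cumhaz <- function(basis, beta, gamma, theta, x, z_starts, Zmat, t) {
  h <- function(s) {
    a <- pmax(findInterval(s, z_starts), 1)
    zt <- Zmat[a, , drop = FALSE]
    drop(basis_psi(basis, s) %*% theta) *
      exp(sum(x * beta) + drop(zt %*% gamma))
  }
  hi <- min(t, basis$b)
  if (hi <= basis$a) return(0)
  cuts <- sort(unique(c(basis$a, z_starts[z_starts > basis$a &
                                            z_starts < hi], hi)))
  out <- 0
  for (j in seq_len(length(cuts) - 1))
    out <- out + stats::integrate(h, cuts[j], cuts[j + 1],
                                  rel.tol = 1e-11, abs.tol = 1e-13,
                                  subdivisions = 2000L)$value
  out
}

# penalised log-likelihood as a plain function of the stacked parameter
# vector, for numeric differentiation
phi_fun <- function(cache, p, q, m, lambda) {
  function(par) {
    mplcox:::.ll_eval(cache, par[seq_len(p)], par[p + seq_len(q)],
                      par[p + q + seq_len(m)], lambda)$phi
  }
}

score_fun <- function(cache, p, q, m, lambda) {
  function(par) {
    e <- mplcox:::.ll_eval(cache, par[seq_len(p)], par[p + seq_len(q)],
                           par[p + q + seq_len(m)], lambda, level = "score")
    c(e$gb, e$gg, e$gt)
  }
}
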