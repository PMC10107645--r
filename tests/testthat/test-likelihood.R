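dat <- make_mixed_data()
basis <- mixed_basis(dat)
cache <- mplcox:::.ll_cache(dat, basis)
m <- basis$m

test_that("segmented cumulative basis reduces and integrates correctly", {
  z_starts <- c(0, 0.5, 1.3)
  Z <- matrix(c(0, 1, 0.4), ncol = 1)
  # gamma = 0: the exponential factors cancel and the sum telescopes
  ps0 <- mplcox:::.traj_psi_star(basis, 0, z_starts, Z, t = c(0.7, 1.9))
  expect_equal(ps0, basis_Psi(basis, c(0.7, 1.9)), tolerance = 1e-12)
  # t = 0 gives the zero vector
  expect_equal(drop(mplcox:::.traj_psi_star(basis, -0.8, z_starts, Z, 0)),
               rep(0, m))
  # three-segment trajectory against numerical integration of
  # psi_u(s) exp(z(s) gamma)
  gam <- -0.8
  ps <- drop(mplcox:::.traj_psi_star(basis, gam, z_starts, Z, 1.9))
  for (u in seq_len(m)) {
    f <- function(s) {
      a <- pmax(findInterval(s, z_starts), 1)
      basis_psi(basis, s)[, u] * exp(Z[a, ] * gam)
    }
    # psi_u carries no mass below the basis support; split the quadrature
    # at the covariate change point inside the support
    cuts <- sort(unique(c(basis$a, z_starts[z_starts > basis$a &
                                              z_starts < 1.9], 1.9)))
    want <- 0
    for (j in seq_len(length(cuts) - 1))
      want <- want + integrate(f, cuts[j], cuts[j + 1], rel.tol = 1e-10,
                               abs.tol = 1e-12, subdivisions = 2000L)$value
    expect_equal(ps[u], want, tolerance = 1e-7)
  }
  # entries are non-negative and non-decreasing in t
  tt <- seq(0, 2.5, by = 0.1)
  PS <- mplcox:::.traj_psi_star(basis, gam, z_starts, Z, tt)
  expect_true(all(PS >= 0))
  expect_true(all(diff(PS) >= -1e-12))
})

test_that("hazard, cumulative hazard and survival satisfy their identities", {
  set.seed(11)
  beta <- c(0.6, -0.4); gam <- -0.7
  theta <- runif(m, 0.3, 1.5)
  x <- c(1, 0.5)
  z_starts <- c(0, 0.9); Z <- matrix(c(0, 1), ncol = 1)
  tq <- mplcox:::.traj_quantities(basis, beta, gam, theta, x, z_starts, Z,
                                  t = c(0, 0.8, 1.4, 2.2))
  expect_equal(tq$H[1], 0)
  expect_equal(tq$S[1], 1)
  expect_true(all(diff(tq$H) > 0))     # strictly rising inside the support
  expect_true(all(tq$S <= 1 & tq$S > 0))
  # H(t) = theta' Psi*(t) e^{x'beta} (compositional identity)
  ps <- mplcox:::.traj_psi_star(basis, gam, z_starts, Z, c(0.8, 1.4))
  expect_equal(tq$H[2:3], drop(ps %*% theta) * exp(sum(x * beta)),
               tolerance = 1e-12)
  # -d/dt log S(t) equals the hazard (central differences, interior t)
  for (t0 in c(1.0, 1.4, 1.9)) {
    h <- 1e-5
    Sm <- mplcox:::.traj_quantities(basis, beta, gam, theta, x, z_starts, Z,
                                    c(t0 - h, t0 + h))$S
    num <- -(log(Sm[2]) - log(Sm[1])) / (2 * h)
    an <- mplcox:::.traj_quantities(basis, beta, gam, theta, x, z_starts, Z,
                                    t0)$h
    expect_equal(num, an, tolerance = 1e-5)
  }
  # theta = 0: hazard identically zero, survival identically one
  tq0 <- mplcox:::.traj_quantities(basis, beta, gam, rep(0, m), x,
                                   z_starts, Z, c(0.8, 1.5))
  expect_equal(tq0$h, c(0, 0))
  expect_equal(tq0$S, c(1, 1))
  # beta = gamma = 0: hazard reduces to the baseline hazard
  tqb <- mplcox:::.traj_quantities(basis, c(0, 0), 0, theta, x, z_starts, Z,
                                   c(0.8, 1.5))
  expect_equal(tqb$h, drop(basis_psi(basis, c(0.8, 1.5)) %*% theta))
})

test_that("log-likelihood matches a per-subject quadrature oracle", {
  set.seed(21)
  beta <- c(0.4, -0.6); gam <- -0.5
  theta <- runif(m, 0.2, 1.2)
  ll <- log_likelihood(dat, basis, beta, gam, theta)
  # oracle: numerically integrated H_i per subject, type-wise contributions
  sub <- dat$subjects
  df <- as.data.frame(dat)
  oracle <- 0
  for (i in seq_len(dat$n)) {
    rows <- df[df$id == sub$id[i], ]
    x <- c(rows$x1[1], rows$x2[1])
    zs <- rows$tstart
    Z <- matrix(rows$z1, ncol = 1)
    Hfun <- function(t) quad_cumhaz(basis, beta, gam, theta, x, zs, Z, t)
    oracle <- oracle + switch(sub$censor_type[i],
      event = {
        y <- sub$y[i]
        zt <- Z[max(findInterval(y, zs), 1), ]
        log(drop(basis_psi(basis, y) %*% theta)) + sum(x * beta) +
          zt * gam - Hfun(y)
      },
      right = -Hfun(sub$yL[i]),
      left = log(1 - exp(-Hfun(sub$yR[i]))),
      interval = log(exp(-Hfun(sub$yL[i])) - exp(-Hfun(sub$yR[i]))))
  }
  expect_equal(ll, oracle, tolerance = 1e-7)
})

test_that("simple closed-form likelihood contributions are exact", {
  # single right-censored subject whose censoring time precedes the basis
  # support: H(yL) = 0, so the subject contributes nothing
  b2 <- mspline_basis(c(1, 2, 3), m = 4)
  d1 <- tvc_data(data.frame(id = 1, tstart = 0, tstop = 0.5, yL = 0.5,
                            yR = Inf, censor_type = "right", x1 = 1, z1 = 0))
  expect_equal(log_likelihood(d1, b2, 0, 0, rep(0.5, 4)), 0)
  # single left-censored subject scaled so that S(yR) = exp(-1)
  d2 <- tvc_data(data.frame(id = 1, tstart = 0, tstop = 2.5, yL = 0,
                            yR = 2.5, censor_type = "left", x1 = 0, z1 = 0))
  cpsi <- sum(basis_Psi(b2, 2.5))
  th <- rep(1 / cpsi, 4)
  expect_equal(log_likelihood(d2, b2, 0, 0, th), log(1 - exp(-1)),
               tolerance = 1e-12)
  # degenerate event: h0(y) = 0 errors
  d3 <- tvc_data(data.frame(id = 1, tstart = 0, tstop = 2, yL = 2, yR = 2,
                            censor_type = "event", x1 = 0, z1 = 0))
  expect_error(log_likelihood(d3, b2, 0, 0, rep(0, 4)),
               "likelihood-degenerate")
})

test_that("penalised objective subtracts exactly the curvature penalty", {
  set.seed(31)
  beta <- rnorm(2, 0, 0.3); gam <- rnorm(1, 0, 0.3)
  theta <- runif(m, 0.1, 1)
  lam <- 0.7
  phi <- penalised_loglik(dat, basis, beta, gam, theta, lam)
  ll <- log_likelihood(dat, basis, beta, gam, theta)
  expect_equal(phi, ll - lam * drop(theta %*% basis$R %*% theta),
               tolerance = 1e-12)
  expect_equal(penalised_loglik(dat, basis, beta, gam, theta, 0), ll)
  expect_lte(phi, ll)
  # affine baseline lies in the penalty null space: Phi = l for any lambda
  grid <- seq(basis$a, basis$b, length.out = 300)
  th_aff <- pmax(qr.solve(basis_psi(basis, grid), 0.8 + 0.3 * grid), 0)
  if (drop(th_aff %*% basis$R %*% th_aff) < 1e-10) {
    expect_equal(penalised_loglik(dat, basis, beta, gam, th_aff, 5),
                 log_likelihood(dat, basis, beta, gam, th_aff),
                 tolerance = 1e-8)
  }
})

test_that("analytic score matches central differences at random points", {
  set.seed(41)
  lam <- 0.35
  f <- phi_fun(cache, 2, 1, m, lam)
  for (rep in 1:20) {
    par <- c(rnorm(2, 0, 0.4), rnorm(1, 0, 0.4), runif(m, 0.15, 1.2))
    e <- mplcox:::.ll_eval(cache, par[1:2], par[3], par[3 + seq_len(m)],
                           lam, level = "score")
    g_an <- c(e$gb, e$gg, e$gt)
    g_num <- num_grad(f, par)
    expect_lt(max(abs(g_an - g_num) / pmax(abs(g_num), 1e-4)), 1e-4)
  }
})

test_that("analytic Hessian matches numerical second differences", {
  set.seed(51)
  for (rep in 1:5) {
    par <- c(rnorm(2, 0, 0.4), rnorm(1, 0, 0.4), runif(m, 0.15, 1.2))
    e <- mplcox:::.ll_eval(cache, par[1:2], par[3], par[3 + seq_len(m)],
                           lambda = 0, level = "hessian")
    Hnum <- num_hess_from_grad(score_fun(cache, 2, 1, m, 0), par)
    expect_lt(max(abs(e$H - Hnum)) / max(abs(Hnum)), 1e-6)
    # block Newton curvatures agree with the corresponding sub-blocks
    eb <- mplcox:::.ll_eval(cache, par[1:2], par[3], par[3 + seq_len(m)],
                            lambda = 0, level = "beta")
    expect_equal(eb$Hbb, e$H[1:2, 1:2], tolerance = 1e-10)
    eg <- mplcox:::.ll_eval(cache, par[1:2], par[3], par[3 + seq_len(m)],
                            lambda = 0, level = "gamma")
    expect_equal(eg$Hgg, e$H[3, 3, drop = FALSE], tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
})

test_that("likelihood is invariant to re-partitioning covariate segments", {
  df <- as.data.frame(dat)
  # split subject 3's single interval into three with equal z values
  r <- df[df$id == 3, ]
  split3 <- rbind(
    transform(r, tstop = 0.5),
    transform(r, tstart = 0.5, tstop = 1.0),
    transform(r, tstart = 1.0))
  df2 <- rbind(df[df$id != 3, ], split3)
  dat2 <- tvc_data(df2)
  cache2 <- mplcox:::.ll_cache(dat2, basis)
  set.seed(61)
  par <- c(rnorm(2, 0, 0.3), -0.4, runif(m, 0.2, 1))
  for (lv in c("ll", "score")) {
    e1 <- mplcox:::.ll_eval(cache, par[1:2], par[3], par[3 + seq_len(m)],
                            0.2, level = lv)
    e2 <- mplcox:::.ll_eval(cache2, par[1:2], par[3], par[3 + seq_len(m)],
                            0.2, level = lv)
    expect_equal(e1$phi, e2$phi, tolerance = 1e-12)
    if (lv == "score") {
      # subject order differs, but the totals must agree
      expect_equal(sort(abs(c(e1$gb, e1$gg, e1$gt))),
                   sort(abs(c(e2$gb, e2$gg, e2$gt))), tolerance = 1e-10)
    }
  }
})

test_that("Hessian and score weights coincide for right/event-only data", {
  cfg <- sim_preset("study1-gompertz", n = 60, seed = 9)
  d1 <- simulate_tvc(cfg)
  b1 <- mixed_basis(d1)
  c1 <- mplcox:::.ll_cache(d1, b1)
  e <- mplcox:::.ll_eval(c1, c(0.3, -0.2), -0.5, runif(b1$m, 0.2, 1),
                         lambda = 0, level = "hessian")
  expect_equal(e$wA, e$wC, tolerance = 1e-12)
  # with interval censoring present the weights must differ
  e2 <- mplcox:::.ll_eval(cache, c(0.3, -0.2), -0.5, runif(m, 0.2, 1),
                          lambda = 0, level = "hessian")
  expect_gt(max(abs(e2$wA - e2$wC)), 1e-6)
})
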