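test_that("closed-form event-time inversion is exact", {
  bl <- mplcox:::.baselines
  # Gompertz: H0(T) = 2.5(e^{0.2T}-1) = -log u
  u <- exp(-2.5)
  T1 <- mplcox:::.invert_piecewise(bl$gompertz, -log(u),
                                   matrix(0, 1, 1), matrix(1, 1, 1))
  expect_equal(bl$gompertz$H0(T1), 2.5, tolerance = 1e-10)
  expect_equal(T1, 5 * log(2), tolerance = 1e-10)
  # Weibull: T = (-log u)^{1/3}
  u2 <- 0.2
  T2 <- mplcox:::.invert_piecewise(bl$weibull, -log(u2),
                                   matrix(0, 1, 1), matrix(1, 1, 1))
  expect_equal(T2, (-log(u2))^(1 / 3), tolerance = 1e-12)
  # every family: H0(H0inv(x)) = x
  for (b in bl) {
    x <- c(0.01, 0.5, 2, 10)
    expect_equal(b$H0(b$H0inv(x)), x, tolerance = 1e-10)
  }
})

test_that("inversion residuals vanish over piecewise covariate trajectories", {
  for (preset in c("study1-gompertz", "study1-exponential", "s2s1-weibull",
                   "s2s1-loglogistic")) {
    cfg <- sim_preset(preset, n = 60, seed = 7)
    dat <- simulate_tvc(cfg)
    sim <- attr(dat, "sim")
    bl <- mplcox:::.baselines[[sim$config$baseline]]
    # recompute H(T) independently, segment by segment, and compare with
    # the exponential deviate q = -log(u) e^{-x'beta}
    for (i in seq_len(20)) {
      s <- sim$seg_starts[i, ]
      f <- sim$fmat[i, ]
      Tt <- sim$T[i]
      H <- 0
      for (a in seq_along(s)) {
        hi <- if (a < length(s)) min(Tt, s[a + 1]) else Tt
        if (hi > s[a]) H <- H + f[a] * (bl$H0(hi) - bl$H0(s[a]))
      }
      expect_lt(abs(H - sim$q[i]), 1e-8)
    }
  }
})

test_that("scenario 2 inversion residuals hold for the continuous covariate", {
  cfg <- sim_preset("s2s2-cond3", n = 12, seed = 13)
  dat <- simulate_tvc(cfg)
  sim <- attr(dat, "sim")
  bl <- mplcox:::.baselines$weibull
  for (i in seq_len(12)) {
    H <- integrate(function(s) bl$h0(s) * exp(1 * sim$taui[i] * sin(2 * s)),
                   0, sim$T[i], rel.tol = 1e-11, abs.tol = 1e-13)$value
    expect_lt(abs(H - sim$q[i]), 1e-8)
  }
  # recorded covariate values are the trajectory sampled at segment starts
  df <- as.data.frame(dat)
  expect_equal(df$z1, sim$taui[df$id] * sin(2 * df$tstart), tolerance = 1e-12)
})

test_that("empirical event proportions match the configured pi_E", {
  cfg <- sim_preset("s2s1-weibull", n = 100000, seed = 3, pi_E = 0.7)
  dat <- simulate_tvc(cfg)
  pe <- mean(dat$subjects$censor_type == "event")
  expect_lt(abs(pe - 0.7), 0.005)
  # study 1: the right-censoring window is calibrated to pi_E
  cfg1 <- sim_preset("study1-gompertz", n = 100000, seed = 3, pi_E = 0.7)
  dat1 <- simulate_tvc(cfg1)
  pe1 <- mean(dat1$subjects$censor_type == "event")
  expect_lt(abs(pe1 - 0.7), 0.01)
  # covariate-change calibration balances pre/post-change subjects
  sim <- attr(dat1, "sim")
  expect_lt(abs(mean(attr(dat1, "sim")$seg_starts[, 2] < sim$T) - 0.5), 0.02)
})

test_that("scenario 1 censoring classification is internally consistent", {
  cfg <- sim_preset("s2s1-weibull", n = 4000, seed = 19, pi_E = 0.5)
  dat <- simulate_tvc(cfg)
  sub <- dat$subjects
  Tt <- attr(dat, "sim")$T
  expect_true(all(c("event", "right", "left", "interval") %in%
                    sub$censor_type))
  it <- sub$censor_type == "interval"
  expect_true(all(sub$yL[it] <= Tt[it] & Tt[it] <= sub$yR[it]))
  le <- sub$censor_type == "left"
  expect_true(all(Tt[le] < sub$yR[le]) && all(sub$yL[le] == 0))
  ri <- sub$censor_type == "right"
  expect_true(all(Tt[ri] > sub$yL[ri]) && all(is.infinite(sub$yR[ri])))
  ev <- sub$censor_type == "event"
  expect_equal(sub$yL[ev], Tt[ev])
})

test_that("scenario 2 classification follows the assessment grid", {
  cfg <- sim_preset("s2s2-cond1", n = 300, seed = 23)
  dat <- simulate_tvc(cfg)
  sub <- dat$subjects
  sim <- attr(dat, "sim")
  expect_false(any(sub$censor_type == "event"))   # no exact events
  for (i in seq_len(dat$n)) {
    s <- sim$assess[[i]]
    Tt <- sim$T[i]
    ty <- sub$censor_type[i]
    if (Tt < s[1]) {
      expect_equal(ty, "left"); expect_equal(sub$yR[i], s[1])
    } else if (Tt > s[length(s)]) {
      expect_equal(ty, "right"); expect_equal(sub$yL[i], s[length(s)])
    } else {
      expect_equal(ty, "interval")
      expect_true(sub$yL[i] <= Tt && Tt <= sub$yR[i])
      expect_true(all(c(sub$yL[i], sub$yR[i]) %in% s))
    }
  }
})

test_that("generated datasets validate and are bit-reproducible", {
  for (preset in c("study1-gompertz", "s2s1-weibull", "s2s1-loglogistic",
                   "s2s2-cond1", "s2s2-cond2", "s2s2-cond3")) {
    d1 <- simulate_tvc(sim_preset(preset, n = 40, seed = 31))
    d2 <- simulate_tvc(sim_preset(preset, n = 40, seed = 31))
    expect_s3_class(d1, "tvc_data")       # constructor re-validates
    expect_identical(as.data.frame(d1), as.data.frame(d2))
    d3 <- simulate_tvc(sim_preset(preset, n = 40, seed = 32))
    expect_false(identical(as.data.frame(d1), as.data.frame(d3)))
  }
})

test_that("study harness self-test: injecting the truth gives zero bias", {
  cfg <- sim_preset("s2s1-weibull", n = 30, seed = 37)
  st <- run_sim_study(cfg, n_reps = 5, seed = 1, estimator = "oracle")
  expect_equal(st$coef$bias, rep(0, 3))
  expect_equal(st$coef$cp, rep(1, 3))
  expect_equal(st$baseline$bias, rep(0, 3))
  expect_equal(st$diagnostics[["n_failed"]], 0)
  # quartile times invert the true baseline distribution
  bl <- mplcox:::.baselines$weibull
  expect_equal(bl$H0(st$quartile_times), -log(1 - c(0.25, 0.5, 0.75)),
               tolerance = 1e-12)
})
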