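# mplcox

Maximum penalised likelihood (MPL) fitting of the **extended Cox model**
— a proportional hazards model whose linear predictor includes
time-varying covariates — for **partly interval-censored** survival data,
where each observation is an exact event time, or a right-, left- or
interval-censored time.

With interval censoring the partial likelihood is unavailable, and
mid-point imputation is known to bias estimates. `mplcox` instead
maximises a penalised full likelihood: the baseline hazard is expanded in
a non-negative cubic M-spline basis,

    h_i(t) = h0(t) exp(x_i'β + z_i(t)'γ),      h0(t) = Σ_u θ_u ψ_u(t),  θ_u ≥ 0,

and the objective Φ = ℓ(β, γ, θ) − λ θ'Rθ adds a curvature penalty
(r_uv = ∫ψ_u'' ψ_v'') so the hazard estimate is smooth. Fitting
alternates Newton steps for β and γ with a multiplicative-iterative step
for θ that preserves non-negativity, plus a projected-Newton refinement
that certifies the Karush–Kuhn–Tucker conditions. The smoothing
parameter is selected automatically by an approximate marginal
likelihood (σ² = 1/(2λ), σ̂² = θ̂'Rθ̂/(m − ν)); standard errors come from
a constrained sandwich covariance that projects out actively constrained
spline coefficients, and predicted survival curves carry delta-method
confidence intervals. Time-varying covariates are piecewise constant on
subject-specific intervals, which need not coincide with the times at
which the event status is assessed.

The package is aimed at biostatisticians analysing cohort data with
periodic follow-up (repeated clinical assessments, lab-confirmed events)
and covariates that change during follow-up (treatment switches,
incarceration episodes, surgery).

## Worked example

```r
library(mplcox)

cfg <- sim_preset("s2s1-weibull", n = 150, seed = 7)   # 70% events, Weibull h0 = 3t^2
dat <- simulate_tvc(cfg)                               # true beta = (1, -0.5), gamma = -1
fit <- mplcox(dat)
summary(fit)
```

```
Extended Cox model (maximum penalised likelihood)
n = 150 ; non-right-censored = 116 ; spline functions = 5
lambda = 0.0318 ; nu = 1.806 ; loglik = -70.6927

   Estimate       SE       z   p-value
x1  1.09435  0.20944  5.2250 1.741e-07 ***
x2 -1.01387  0.34448 -2.9432  0.003248 **
z1 -0.68064  0.20533 -3.3148  0.000917 ***
---
Actively constrained baseline coefficients: 1
```

Both time-fixed covariates and the time-varying covariate `z1` (true
effect -1, somewhat attenuated by smoothing at this sample size) come out
significant with the expected signs; one spline coefficient sits on its
non-negativity boundary and is projected out of the covariance. Predicted
survival with point-wise 95% delta-method intervals for a subject whose
`z1` switches on at t = 0.5:

```r
predict(fit, times = c(0.25, 0.5, 0.75, 1), x = c(1, 0.5),
        z_times = c(0, 0.5), z_values = c(0, 1))
```

```
  time      surv         se     lower     upper
1 0.25 0.9552419 0.01585423 0.9241682 0.9863157
2 0.50 0.7765043 0.03907220 0.6999242 0.8530844
3 0.75 0.6033062 0.04832319 0.5085944 0.6980179
4 1.00 0.3708776 0.05721271 0.2587427 0.4830124
```

Datasets are plain long-format CSV (one row per covariate-constancy
interval; see `?tvc_data`), and a small command line ships in
`exec/mplcox`:

```sh
mplcox simulate --preset s2s1-weibull --n 200 --seed 1 --out sim.csv
mplcox fit --data sim.csv --out-dir fit1
mplcox predict --fit fit1 --profiles profiles.csv --grid 0:1.5:50
mplcox study --preset s2s2-cond1 --reps 100 --n 200 --seed 1 --out table.csv
```

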