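# Replicated-study results shared across test files (computed once per
# test session; the partly-interval-censored regime is the costly one).
.study_cache <- new.env(parent = emptyenv())

cached_s2s1_study <- function() {
  if (is.null(.study_cache$s2s1)) {
    cfg <- sim_preset("s2s1-weibull", n = 200, pi_E = 0.7, seed = 5)
    .study_cache$s2s1 <- suppressWarnings(
      run_sim_study(cfg, n_reps = 120, seed = 424242,
                    control = mplcox_control(kkt_tol = 1e-4)))
  }
  .study_cache$s2s1
}
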