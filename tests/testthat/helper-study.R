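# One shared simulation study for the regression checks: 100 replicates of
# the default scenario (n = 150, beta1 = (0.5, 0.5), beta2 = (0, -0.5),
# tau_c = 63), each fitted by the smooth method with its sandwich covariance.
# Cached so that recovery and coverage checks reuse the same fits.
lee_study <- local({
  cache <- NULL
  function(reps = 100) {
    if (is.null(cache)) {
      res <- lapply(seq_len(reps), function(r) {
        tab <- sim_bivgap(sim_scenario(seed = 20000 + r))
        fit <- bivgap_reg(tab, n_resample = 200, seed = 30000 + r)
        list(est = coef(fit), se = fit$se)
      })
      cache <<- list(est = t(sapply(res, `[[`, "est")),
                     se = t(sapply(res, `[[`, "se")),
                     truth = c(0.5, 0.5, 0, -0.5))
    }
    cache
  }
})
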