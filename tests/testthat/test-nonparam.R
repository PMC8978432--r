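test_that("risk and jump functions reproduce hand computations on T1", {
  rj <- risk_jump_functions(t1_table())
  expect_equal(rj$R(2), 1)
  expect_equal(rj$R(5), 5 / 6)
  expect_equal(rj$R(7), 1 / 6)
  expect_equal(rj$H(2, Inf, Inf), 1 / 6)
  expect_equal(rj$H(5, Inf, Inf), 1 / 3)
  expect_equal(rj$H(7, Inf, Inf), 1 / 6)
  expect_equal(rj$H(5, 0, 0), 0)          # all gaps positive
  expect_equal(rj$t_star, c(2, 5, 7))
  expect_equal(rj$tau_c_hat, 12)
  # R-hat non-increasing, H-hat <= R-hat at every jump time
  Rv <- vapply(rj$t_star, rj$R, 0)
  expect_true(all(diff(Rv) <= 0))
  expect_true(all(vapply(rj$t_star, function(t) rj$H(t, Inf, Inf), 0) <= Rv))
})

test_that("joint CDF matches hand evaluation on T1 and flags the support", {
  tab <- t1_table()
  jc <- joint_cdf(tab, u1 = c(2, 4), u2 = c(2, 4))
  expect_equal(jc$cdf[jc$x == 2 & jc$y == 2], 1 / 6)
  expect_equal(jc$cdf[jc$x == 4 & jc$y == 4], 1)
  # x + y beyond the largest follow-up is flagged, never extrapolated
  far <- joint_cdf(tab, u1 = 10, u2 = 10)
  expect_true(is.na(far$cdf))
})

test_that("marginal survival matches the hand product-limit on T1", {
  ms <- marginal_survival(t1_table(), times = c(0.5, 1, 2, 3))
  expect_equal(ms$survival, c(1, 5 / 6, 1 / 2, 1 / 3))
  expect_true(all(diff(ms$survival) <= 0))
})

test_that("conditional CDF is the ratio of joint mass to Type I mass", {
  tab <- t1_table()
  cc <- conditional_cdf(tab, interval = c(0, 2), y_grid = c(0.5, 2))
  expect_equal(cc$cdf[2], (1 / 6) / (1 / 2))
  expect_equal(cc$cdf[1], 0)              # below the smallest uncensored Y
  expect_error(conditional_cdf(tab, c(2, 2), y_grid = 1), "v1 < v2")
  expect_error(conditional_cdf(tab, c(20, 30), y_grid = 1), "mass")
})

test_that("joint CDF and marginal survival match brute-force oracles", {
  for (seed in 1:6) {
    tab <- random_table(seed, n = sample(3:6, 1))
    for (ai in 1:2) {
      rj <- risk_jump_functions(tab, ai = ai)
      pts <- expand.grid(x = c(1.5, 3, 6), y = c(1, 4))
      got <- joint_cdf(rj, u1 = c(1.5, 3, 6), u2 = c(1, 4))
      for (r in seq_len(nrow(got))) {
        if (is.na(got$cdf[r])) next
        expect_equal(got$cdf[r],
                     brute_joint_cdf(tab, got$x[r], got$y[r], ai = ai),
                     tolerance = 1e-12)
      }
      for (x in c(1, 2.5, 4.5))
        expect_equal(marginal_survival(rj, times = x)$survival,
                     brute_marginal_surv(tab, x, ai = ai),
                     tolerance = 1e-12)
    }
  }
})

test_that("joint CDF telescopes to the total-gap product limit", {
  # evaluated beyond all observed gaps, the joint CDF equals
  # 1 - S_Z(tau), the survival implied by its own prefactors
  tested <- 0
  for (seed in 1:10) {
    tab <- random_table(seed)
    rj <- risk_jump_functions(tab)
    xm <- max(rj$xs); ym <- max(rj$ys)
    if (xm + ym > rj$tau_c_hat) next    # evaluation point outside support
    full <- joint_cdf(rj, u1 = xm, u2 = ym)$cdf
    Hinf <- vapply(rj$t_star, function(t) rj$H(t, Inf, Inf), 0)
    Rk <- vapply(rj$t_star, rj$R, 0)
    expect_equal(full, 1 - prod(1 - Hinf / Rk), tolerance = 1e-12)
    tested <- tested + 1
  }
  expect_gte(tested, 3)
  expect_equal(joint_cdf(t1_table(), 6, 6)$cdf, 1)
})

test_that("monotonicity holds along both axes on simulated data", {
  tab <- sim_bivgap(sim_scenario(nsize = 60, seed = 5))
  u <- seq(1, 25, by = 3)
  jc <- joint_cdf(tab, u, u)
  for (yv in u) {
    col <- jc$cdf[jc$y == yv]
    expect_true(all(diff(col[!is.na(col)]) >= -1e-12))
  }
  for (xv in u) {
    row <- jc$cdf[jc$x == xv]
    expect_true(all(diff(row[!is.na(row)]) >= -1e-12))
  }
  ms <- marginal_survival(tab)
  expect_true(all(diff(ms$survival) <= 1e-12))
  cc <- conditional_cdf(tab, c(2, 10), y_grid = u)
  expect_true(all(diff(cc$cdf) >= -1e-12))
  expect_true(all(cc$cdf >= 0 & cc$cdf <= 1))
})

test_that("the two weight choices agree on large simulated data", {
  tab <- sim_bivgap(sim_scenario(nsize = 400, seed = 17))
  u <- c(3, 8, 15)
  j1 <- joint_cdf(tab, u, u, ai = 1)
  j2 <- joint_cdf(tab, u, u, ai = 2)
  np <- bivgap_np(tab, u1 = u, u2 = u, n_boot = 60, seed = 1)
  ok <- !is.na(j1$cdf)
  expect_true(all(abs(j1$cdf[ok] - j2$cdf[ok]) <= 3 * np$joint_cdf$se[ok]))
})

test_that("marginal survival recovers the true law of Type I gaps", {
  # lognormal margin: log X ~ N(mu, sd^2) with sd^2 = frailty + error var
  reps <- 10
  xq <- exp(1.1 + sqrt(0.5) * qnorm(c(0.2, 0.4, 0.6, 0.8)))
  truth <- 1 - pnorm((log(xq) - 1.1) / sqrt(0.5))
  est <- matrix(0, reps, length(xq))
  for (r in seq_len(reps)) {
    scn <- sim_scenario(nsize = 500, beta1 = c(0, 0), beta2 = c(0, 0),
                        tau_c = 63, seed = 700 + r)
    est[r, ] <- marginal_survival(sim_bivgap(scn), times = xq)$survival
  }
  expect_lt(max(abs(colMeans(est) - truth)), 0.05)
})

test_that("the bootstrap is seeded, clipped and guarded", {
  tab <- t1_table()
  np1 <- bivgap_np(tab, u1 = c(2, 4), u2 = c(2, 4), n_boot = 50, seed = 9)
  np2 <- bivgap_np(tab, u1 = c(2, 4), u2 = c(2, 4), n_boot = 50, seed = 9)
  expect_identical(np1$joint_cdf, np2$joint_cdf)
  expect_identical(np1$marginal_survival, np2$marginal_survival)
  expect_true(all(np1$joint_cdf$ci_low >= 0 & np1$joint_cdf$ci_high <= 1,
                  na.rm = TRUE))
  expect_error(bivgap_np(tab, n_boot = 1), "n_boot")

  # identical subjects: resampling cannot move the estimate
  df <- t1_df()[t1_df()$id == 1, ]
  many <- do.call(rbind, lapply(1:4, function(k) transform(df, id = k)))
  same <- episode_table(many)
  nps <- bivgap_np(same, u1 = 2, u2 = 3, n_boot = 25, seed = 1)
  expect_equal(nps$joint_cdf$se, 0)
  expect_equal(nps$marginal_survival$se, rep(0, nrow(nps$marginal_survival)))
})

test_that("configuration gates match the documented ranges", {
  tab <- t1_table()
  expect_error(bivgap_np(tab, level = 0.3), "0.50 and 0.99")
  expect_error(bivgap_np(tab, level = 0.995), "0.50 and 0.99")
  expect_error(bivgap_np(tab, conditional = TRUE), "given_interval")
  expect_error(bivgap_np(tab, ai = 3), "1 or 2")
  np <- bivgap_np(tab, level = 0.99, conditional = TRUE,
                  given_interval = c(0, 3), n_boot = 25, seed = 2)
  expect_equal(np$level, 0.99)
  expect_equal(np$given_interval, c(0, 3))
  expect_s3_class(np$conditional_cdf, "data.frame")
  h <- head(np)
  expect_named(h, c("joint_cdf", "marginal_survival", "conditional_cdf"))
})
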