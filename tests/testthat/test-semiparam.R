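test_that("transformed gap times follow the displayed formulas", {
  tab <- t1_table(c(1, 0, 1))
  # b = 0 is the identity transform
  tr0 <- chang_transform(tab, c(0, 0))
  expect_equal(tr0$xt, tab$data$xij)
  expect_equal(tr0$zt, tab$data$zij)

  # single subject, A = 1, b1 = log 2, b2 = 0, episode (4, 2), C = 20
  one <- episode_table(data.frame(
    id = c("s", "s"), epi = 1:2, xij = c(4, 3), yij = c(2, 1),
    d1 = c(1, 1), d2 = c(1, 0), a = c(1, 1)),
    covariates = "a", validate = FALSE)
  tr <- chang_transform(one, c(log(2), 0))
  expect_equal(tr$xt0[1], 2)
  expect_equal(tr$zt0[1], 4)

  # row-by-row recomputation on T1 with a binary covariate
  tr <- chang_transform(tab, c(0.5, -0.5))
  df <- tab$data
  for (s in tab$subjects) {
    rows <- which(df$id == s)
    a <- df$a1[rows[1]]
    ci <- sum(df$zij[rows])
    cum <- 0
    for (j in seq_along(rows)) {
      x0 <- df$xij[rows[j]] * exp(-0.5 * a)
      z0 <- x0 + df$yij[rows[j]] * exp(0.5 * a)
      bound <- ci * exp(-0.5 * a) - cum
      expect_equal(tr$xt[rows[j]], min(x0, bound))
      expect_equal(tr$zt[rows[j]], min(z0, bound))
      cum <- cum + min(z0, bound)
    }
  }
})

test_that("rank-based estimating functions vanish under no contrast", {
  # identical covariates: the risk-set mean equals every subject's value
  tab <- t1_table(c(1, 1, 1))
  for (b in list(c(0, 0), c(0.7, -0.3), c(-1, 2))) {
    u <- chang_U(tab, b)
    expect_equal(unname(u$U1), 0)
    expect_equal(unname(u$U2), 0)
  }
  one <- episode_table(data.frame(
    id = 1, epi = 1:2, xij = c(2, 3), yij = c(1, 1),
    d1 = 1, d2 = c(1, 0), a = 1), covariates = "a", validate = FALSE)
  u1 <- chang_U(one, c(0.2, 0.1))
  expect_equal(unname(u1$U1), 0)
  expect_equal(unname(u1$U2), 0)
})

test_that("rank-based estimating functions match the brute-force oracle", {
  tab <- t1_table(c(1, 0, 0))
  for (b in list(c(0, 0), c(0.3, -0.2))) {
    got <- chang_U(tab, b)
    want <- brute_chang_U(tab, b)
    expect_equal(unname(got$U1), unname(want$U1), tolerance = 1e-12)
    expect_equal(unname(got$U2), unname(want$U2), tolerance = 1e-12)
  }
  for (seed in 1:4) {
    tab <- random_table(seed, n = sample(3:6, 1), with_covariate = TRUE)
    for (b in list(c(0, 0), c(0.4, 0.6), c(-0.5, 0.2))) {
      got <- chang_U(tab, b)
      want <- brute_chang_U(tab, b)
      expect_equal(unname(got$U1), unname(want$U1), tolerance = 1e-12)
      expect_equal(unname(got$U2), unname(want$U2), tolerance = 1e-12)
    }
  }
})

test_that("the rank-based solver recovers a null effect and errors honestly", {
  reps <- 16
  ests <- t(sapply(seq_len(reps), function(r) {
    scn <- sim_scenario(nsize = 150, beta1 = c(0, 0), beta2 = c(0, 0),
                        seed = 5000 + r)
    fit <- bivgap_reg(sim_bivgap(scn), method = "chang", se = FALSE)
    coef(fit)
  }))
  # null effects recovered within 3 Monte-Carlo SEs of zero
  expect_true(all(abs(colMeans(ests)) <
                    3 * apply(ests, 2, sd) / sqrt(reps)))

  tab <- sim_bivgap(sim_scenario(nsize = 40, seed = 2))
  tab$data$const <- 1
  tab$covariate_names <- c("a1", "a2", "const")
  expect_error(bivgap_reg(tab, covariates = "const", method = "chang",
                          se = FALSE),
               "^Error: Max Iterations reached. Did not converge.$")
  expect_error(bivgap_reg(tab, covariates = "a1", method = "chang",
                          max_iter = 0, se = FALSE),
               "^Error: Max Iterations reached. Did not converge.$")
})

test_that("perturbed-equation resampling is seeded and well formed", {
  tab <- sim_bivgap(sim_scenario(nsize = 50, seed = 12))
  rc <- bivgap:::reg_core(tab, c("a1", "a2"))
  fit <- solve_chang(rc)
  expect_error(parzen_resample_vcov(tab, fit, n_resample = 1),
               "n_resample")
  V1 <- parzen_resample_vcov(tab, fit, n_resample = 20, seed = 4)
  V2 <- parzen_resample_vcov(tab, fit, n_resample = 20, seed = 4)
  expect_identical(V1, V2)
  expect_equal(V1, t(V1))
  expect_true(all(eigen(V1, symmetric = TRUE, only.values = TRUE)$values >
                    -1e-10))
  expect_true(all(is.finite(sqrt(diag(V1)))))
})

test_that("censoring Kaplan-Meier treats censoring as the event", {
  # no censoring events in episode 1
  df <- data.frame(id = rep(1:3, each = 2), epi = rep(1:2, 3),
                   xij = rep(c(2, 3), 3), yij = c(1, 1, 2, 1, 1, 1),
                   d1 = 1, d2 = rep(c(1, 0), 3))
  expect_message(km <- censoring_km(episode_table(df), which = 1),
                 "identically 1")
  expect_equal(km$G(c(1, 5, 10)), c(1, 1, 1))

  # three first-episode times, all censoring events: steps 2/3, 1/3, 0
  km2 <- bivgap:::km_from_vectors(c(2, 5, 7), c(1, 1, 1), L = 7, which = 1)
  expect_equal(km2$G(c(2, 5, 7)), c(2 / 3, 1 / 3, 0))

  # T1, which = 1: first-episode X = (2, 1, 5), censoring indicators
  # 1 - d1 = (0, 0, 1): the estimate drops only at t = 5
  km3 <- censoring_km(t1_table(), which = 1)
  expect_equal(km3$G(c(2, 4.9)), c(1, 1))
  expect_equal(km3$G(5), 0)
})

test_that("the comparison kernel is symmetric, bounded and guarded", {
  expect_equal(o_kernel(10, 10, 10), 0)
  expect_equal(o_kernel(1, 2, 10), log(2) - log(10))
  set.seed(1)
  s <- runif(20, 0.1, 30); t <- runif(20, 0.1, 30)
  expect_equal(o_kernel(s, t, 12), o_kernel(t, s, 12))
  expect_true(all(o_kernel(s, t, 12) <= 0))
  expect_error(o_kernel(-1, 2, 10), "positive")
  expect_error(o_kernel(1, 2, 0), "positive")
})

test_that("U-statistic estimating functions match the quadruple loop", {
  # hand-size data: two subjects, one covariate
  df <- data.frame(id = c(1, 1, 2, 2), epi = c(1, 2, 1, 2),
                   xij = c(2, 1, 3, 2), yij = c(1, 0.5, 2, 1),
                   d1 = 1, d2 = c(1, 0, 1, 0), a = c(0, 0, 1, 1))
  tab <- episode_table(df, covariates = "a")
  km1 <- censoring_km(tab, 1); km2 <- censoring_km(tab, 2)
  for (b in list(c(0, 0), c(0.5, -0.5))) {
    got <- lee_D(tab, b)
    want <- brute_lee_D(tab, b, km1, km2)
    expect_equal(unname(got$D1), unname(want$D1), tolerance = 1e-12)
    expect_equal(unname(got$D2), unname(want$D2), tolerance = 1e-12)
  }
  for (seed in 5:8) {
    tab <- random_table(seed, n = 4, with_covariate = TRUE)
    km1 <- censoring_km(tab, 1); km2 <- censoring_km(tab, 2)
    for (b in list(c(0, 0), c(-0.3, 0.4))) {
      got <- lee_D(tab, b)
      want <- brute_lee_D(tab, b, km1, km2)
      expect_equal(unname(got$D1), unname(want$D1), tolerance = 1e-12)
      expect_equal(unname(got$D2), unname(want$D2), tolerance = 1e-12)
    }
  }
  expect_error(lee_D(t1_table(c(1, 1, 1)), c(0, 0)),
               "no covariate variation")
})

test_that("the smooth estimating function is monotone in each coefficient", {
  tab <- sim_bivgap(sim_scenario(nsize = 30, seed = 21))
  km1 <- censoring_km(tab, 1); km2 <- censoring_km(tab, 2)
  rc <- bivgap:::reg_core(tab, c("a1", "a2"))
  for (k in 1:2) {
    grid <- seq(-1, 1, by = 0.25)
    vals <- sapply(grid, function(v) {
      b1 <- c(0.2, -0.2); b1[k] <- v
      bivgap:::lee_D1(rc, b1, km1)[k]
    })
    expect_true(all(diff(vals) > 0))
  }
})

test_that("the smooth solver is deterministic and its variance well formed", {
  tab <- sim_bivgap(sim_scenario(nsize = 80, seed = 31))
  f1 <- bivgap_reg(tab, n_resample = 40, seed = 8)
  f2 <- bivgap_reg(tab, n_resample = 40, seed = 8)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$vcov, f2$vcov)
  expect_equal(f1$vcov, t(f1$vcov))
  ev <- eigen(f1$vcov, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-10))
  expect_lt(f1$residual_norm, 1e-8)
  expect_error(bivgap_reg(tab, method = "lee", max_iter = 0, se = FALSE),
               "^Error: Max Iterations reached. Did not converge.$")
})

test_that("both methods are location-invariant and scale-equivariant", {
  tab <- sim_bivgap(sim_scenario(nsize = 60, seed = 41))
  base_lee <- coef(bivgap_reg(tab, se = FALSE))
  base_chang <- coef(bivgap_reg(tab, method = "chang", se = FALSE))

  shift <- tab
  shift$data$a2 <- shift$data$a2 + 5
  expect_equal(coef(bivgap_reg(shift, se = FALSE)), base_lee,
               tolerance = 1e-6)
  # the rank-based equations are exactly scale-equivariant (U scales with
  # the covariate, the root maps to b/k); location invariance of their Type
  # II part holds only in the limit, because the transformed total gap
  # mixes the two exponential scales
  k <- 4
  scale_c <- tab
  scale_c$data$a2 <- scale_c$data$a2 * k
  for (b in list(c(0.4, 0.2, -0.1, 0.3), c(-0.2, 0.5, 0.3, 0))) {
    bs <- b / c(1, k, 1, k)
    u0 <- chang_U(tab, b)
    us <- chang_U(scale_c, bs)
    expect_equal(unname(us$U1), unname(u0$U1) * c(1, k), tolerance = 1e-10)
    expect_equal(unname(us$U2), unname(u0$U2) * c(1, k), tolerance = 1e-10)
  }

  scale <- tab
  scale$data$a2 <- scale$data$a2 * 4
  sc_lee <- coef(bivgap_reg(scale, se = FALSE))
  expect_equal(sc_lee[c(2, 4)], base_lee[c(2, 4)] / 4, tolerance = 1e-6)
  expect_equal(sc_lee[c(1, 3)], base_lee[c(1, 3)], tolerance = 1e-6)
})

test_that("summary accessors follow Wald arithmetic and guard their inputs", {
  tab <- sim_bivgap(sim_scenario(nsize = 60, seed = 51))
  fit <- bivgap_reg(tab, n_resample = 40, seed = 3)

  # z and two-sided p from estimate 0.56, SE 0.207
  mock <- fit
  mock$coefficients[1] <- 0.56
  mock$se[1] <- 0.207
  s <- summary(mock)$table
  expect_equal(s$z[1], 0.56 / 0.207, tolerance = 1e-12)
  expect_equal(2 * pnorm(-0.56 / 0.207), 0.00682, tolerance = 1e-3)

  ci <- confint(fit, level = 0.95)
  expect_equal(unname(ci[, 1]), unname(coef(fit) - qnorm(0.975) * fit$se))
  one <- confint(fit, parm = "xij a1")
  expect_equal(rownames(one), "xij a1")
  expect_error(confint(fit, parm = "bogus"), "valid names")
  expect_equal(dim(vcov(fit)), c(4, 4))

  broken <- fit
  broken$converged <- FALSE
  expect_error(coef(broken), "converge")

  f <- withr::local_tempfile(fileext = ".csv")
  write_fit(fit, f)
  expect_gt(nrow(read.csv(f)), 0)
  j <- withr::local_tempfile(fileext = ".json")
  write_fit(fit, j, format = "json")
  expect_equal(jsonlite::read_json(j)$method, "lee")
})
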