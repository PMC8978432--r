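#' Weighted risk and jump functions for total gap times
#'
#' Computes the empirical building blocks of the nonparametric joint
#' distribution estimator: the jump function
#' \deqn{\hat H_a(z, (x, y)) = n^{-1} \sum_i \frac{a_i I(m_i \ge 2)}{m_i^*}
#'   \sum_{j \le m_i^*} I(Z_{ij} = z, X_{ij} \le x, Y_{ij} \le y)}
#' and the at-risk function
#' \deqn{\hat R_a(z) = n^{-1} \sum_i \frac{a_i}{m_i^*}
#'   \sum_{j \le m_i^*} I(Z_{ij} \ge z),}
#' where \eqn{Z_{ij} = X_{ij} + Y_{ij}} and \eqn{m_i^*} is the effective
#' episode count. The weight is \eqn{a_i = 1} (`ai = 1`, default) or
#' \eqn{a_i = C_i} (`ai = 2`), with the censoring time \eqn{C_i} reconstructed
#' as the subject's total observed follow-up.
#'
#' @param table a validated [episode_table()].
#' @param ai weight selector, 1 or 2.
#' @return An object of class `risk_jump` with the distinct uncensored total
#'   gap times `t_star`, evaluator functions `H(z, x, y)` and `R(z)`, the
#'   estimated maximal support `tau_c_hat` (largest subject follow-up), and
#'   the per-episode arrays used by downstream estimators.
#' @export
risk_jump_functions <- function(table, ai = 1) {
  core <- np_core(table, ai)
  structure(core, class = "risk_jump")
}

# internal: per-episode arrays for the estimators, j <= m_i^* only
np_core <- function(table, ai = 1) {
  stopifnot(inherits(table, "episode_table"))
  if (!ai %in% c(1, 2)) stop("`ai` must be 1 or 2", call. = FALSE)
  df <- table$data
  idx <- match(df$id, table$subjects)
  build_core(
    n = table$n,
    episode = df$episode, subj = idx,
    x = df$xij, y = df$yij, d1 = df$d1, d2 = df$d2,
    m = unname(table$m), m_star = unname(table$m_star),
    ci = unname(table$ci), ai = ai
  )
}

# assemble arrays from raw subject-indexed episode vectors; reused verbatim by
# the bootstrap, which only remaps `subj` after resampling
build_core <- function(n, episode, subj, x, y, d1, d2, m, m_star, ci, ai) {
  keep <- episode <= m_star[subj]
  s <- subj[keep]
  a <- if (ai == 2) ci else rep(1, length(m))
  w <- (a[s] / m_star[s]) / n              # weight of one episode in R-hat
  jw <- w * (m[s] >= 2)                    # and in H-hat
  xs <- x[keep]; ys <- y[keep]; zs <- xs + ys
  d1k <- d1[keep]; d2k <- d2[keep]
  list(
    n = n, ai = ai,
    xs = xs, ys = ys, zs = zs,
    d1 = d1k, d2 = d2k, subj = s,
    w = w, jw = jw,
    m = m, m_star = m_star, ci = ci,
    t_star = sort(unique(zs[d2k == 1])),
    x_star = sort(unique(xs[d1k == 1 & m[s] >= 2])),
    tau_c_hat = max(ci),
    H = function(z, x_, y_) sum(jw[zs == z & xs <= x_ & ys <= y_]),
    R = function(z) sum(w[zs >= z])
  )
}

#' @export
print.risk_jump <- function(x, ...) {
  cat(sprintf(
    "Risk/jump functions: %d subjects, %d episodes (j <= m*), ai = %d\n",
    x$n, length(x$zs), x$ai))
  cat(sprintf("  %d distinct uncensored total gap times; tau_c_hat = %g\n",
              length(x$t_star), x$tau_c_hat))
  invisible(x)
}

# product-limit machinery shared by the joint cdf and the normalization
# identity: prefactor_k = prod_{l<k} {1 - H(t_l, Inf, Inf)/R(t_l)}
joint_pieces <- function(core) {
  tk <- core$t_star
  if (!length(tk)) stop("no uncensored episodes", call. = FALSE)
  Hinf <- vapply(tk, function(t) core$H(t, Inf, Inf), 0)
  Rk <- vapply(tk, core$R, 0)
  pref <- cumprod(c(1, 1 - Hinf / Rk))[seq_along(tk)]
  list(tk = tk, Hinf = Hinf, Rk = Rk, pref = pref)
}

#' Nonparametric joint CDF of the two gap types
#'
#' Evaluates the product-limit-weighted estimator of
#' \eqn{F_{X^0,Y^0}(x, y) = \Pr(X^0 \le x, Y^0 \le y)} on the grid
#' `u1` \eqn{\times} `u2`:
#' \deqn{\hat F(x, y) = \sum_{t_k^* \le x + y} \prod_{l < k}
#'   \left\{1 - \frac{\hat H_a(t_l^*, \infty)}{\hat R_a(t_l^*)}\right\}
#'   \frac{\hat H_a(t_k^*, (x, y))}{\hat R_a(t_k^*)}.}
#' Grid points with \eqn{x + y} beyond the estimated maximal support
#' `tau_c_hat` are returned as `NA`, never extrapolated.
#'
#' @param rj a [risk_jump_functions()] object (or an `episode_table`, in which
#'   case the risk/jump functions are computed with weight `ai`).
#' @param u1,u2 grids of nonnegative Type I / Type II time values.
#' @param ai weight selector used when `rj` is an `episode_table`.
#' @return data frame with columns `x`, `y`, `cdf`, carrying `tau_c_hat` as an
#'   attribute.
#' @export
joint_cdf <- function(rj, u1, u2, ai = 1) {
  core <- if (inherits(rj, "episode_table")) np_core(rj, ai) else rj
  grid <- expand.grid(x = u1, y = u2, KEEP.OUT.ATTRS = FALSE)
  grid$cdf <- joint_cdf_eval(core, grid$x, grid$y)
  attr(grid, "tau_c_hat") <- core$tau_c_hat
  grid
}

# vectorized evaluator used by the public function and the bootstrap:
# loops over the distinct jump times, accumulating each one's weighted mass
# into every grid point it reaches
joint_cdf_eval <- function(core, x, y) {
  p <- joint_pieces(core)
  out <- numeric(length(x))
  coef <- p$pref / p$Rk
  jump <- core$jw > 0
  for (k in seq_along(p$tk)) {
    sel <- which(jump & core$zs == p$tk[k])
    active <- which(p$tk[k] <= x + y)
    if (!length(sel) || !length(active)) next
    hit <- outer(core$xs[sel], x[active], "<=") &
      outer(core$ys[sel], y[active], "<=")
    out[active] <- out[active] +
      coef[k] * colSums(core$jw[sel] * hit)
  }
  out[x + y > core$tau_c_hat] <- NA_real_
  out
}

#' Marginal survival of Type I gap times
#'
#' Product-limit estimator of \eqn{S_{X^0}(x) = \Pr(X^0 > x)} over the
#' distinct uncensored Type I gap times \eqn{x_k^*}:
#' \deqn{\hat S_{X^0}(x) = \prod_{x_k^* \le x}
#'   \left\{1 - \hat H_X(x_k^*) / \hat R_X(x_k^*)\right\},}
#' with \eqn{\hat H_X} and \eqn{\hat R_X} the Type-I-gap analogues of the
#' weighted jump and at-risk functions (same \eqn{m_i^*} weighting).
#'
#' @inheritParams joint_cdf
#' @param times evaluation times; defaults to the distinct uncensored Type I
#'   gap times.
#' @return data frame with columns `time` and `survival`, with the
#'   left-continuous evaluator attached as attribute `"sfun"`.
#' @export
marginal_survival <- function(rj, times = NULL, ai = 1) {
  core <- if (inherits(rj, "episode_table")) np_core(rj, ai) else rj
  xk <- core$x_star
  if (!length(xk)) stop("no uncensored Type I gap times", call. = FALSE)
  Hx <- vapply(xk, function(t) sum(core$jw[core$xs == t]), 0)
  Rx <- vapply(xk, function(t) sum(core$w[core$xs >= t]), 0)
  surv_k <- cumprod(1 - Hx / Rx)
  sfun <- stepfun(xk, c(1, surv_k), right = FALSE)
  if (is.null(times)) times <- xk
  out <- data.frame(time = times, survival = sfun(times))
  attr(out, "sfun") <- sfun
  out
}

#' Conditional CDF of Type II gaps given an interval of Type I gaps
#'
#' Estimates \eqn{\Pr(Y^0 \le y \mid v_1 \le X^0 \le v_2)} by
#' \deqn{\frac{\hat F(v_2, y) - \hat F(v_1, y)}
#'      {\hat S_{X^0}(v_1) - \hat S_{X^0}(v_2)},}
#' the ratio of the estimated joint mass on the Type I interval to the
#' estimated Type I mass. Setting `interval[1] = 0` gives the single-bound
#' conditional \eqn{\hat F(x, y) / \{1 - \hat S_{X^0}(x)\}}. Because the
#' numerator and denominator are estimated separately, the raw ratio can fall
#' outside \eqn{[0, 1]} in finite samples; estimates are clipped into
#' \eqn{[0, 1]} and the raw values retained in column `raw`.
#'
#' @inheritParams joint_cdf
#' @param interval numeric pair `c(v1, v2)` with `v1 < v2`.
#' @param y_grid evaluation times for the Type II gap.
#' @return data frame with columns `y`, `cdf` (clipped), `raw`.
#' @export
conditional_cdf <- function(rj, interval, y_grid, ai = 1) {
  core <- if (inherits(rj, "episode_table")) np_core(rj, ai) else rj
  if (length(interval) != 2L || !(interval[1] < interval[2]))
    stop("`interval` must be c(v1, v2) with v1 < v2", call. = FALSE)
  v1 <- interval[1]; v2 <- interval[2]
  sf <- attr(marginal_survival(core), "sfun")
  denom <- sf(v1) - sf(v2)
  if (denom <= 0)
    stop("no Type I gap-time mass in the conditioning interval", call. = FALSE)
  num <- joint_cdf_eval(core, rep(v2, length(y_grid)), y_grid) -
    joint_cdf_eval(core, rep(v1, length(y_grid)), y_grid)
  raw <- num / denom
  data.frame(y = y_grid, cdf = pmin(pmax(raw, 0), 1), raw = raw)
}

# resample whole subjects; redraw (up to 10 times) replicates in which no
# uncensored episode survives the draw
resample_core <- function(tab_arrays, ai) {
  for (attempt in 1:10) {
    pick <- sample.int(tab_arrays$n, replace = TRUE)
    rows <- unlist(tab_arrays$rows_by_subj[pick], use.names = FALSE)
    subj <- rep(seq_along(pick), tab_arrays$m[pick])
    core <- build_core(
      n = tab_arrays$n,
      episode = tab_arrays$episode[rows], subj = subj,
      x = tab_arrays$x[rows], y = tab_arrays$y[rows],
      d1 = tab_arrays$d1[rows], d2 = tab_arrays$d2[rows],
      m = tab_arrays$m[pick], m_star = tab_arrays$m_star[pick],
      ci = tab_arrays$ci[pick], ai = ai
    )
    if (length(core$t_star)) return(core)
  }
  NULL
}

# raw arrays kept subject-indexed so resampling is a cheap row lookup
tab_arrays <- function(table) {
  df <- table$data
  idx <- match(df$id, table$subjects)
  list(
    n = table$n,
    episode = df$episode, x = df$xij, y = df$yij, d1 = df$d1, d2 = df$d2,
    m = unname(table$m), m_star = unname(table$m_star), ci = unname(table$ci),
    rows_by_subj = split(seq_len(nrow(df)), idx)
  )
}

#' Nonparametric analysis of bivariate alternating gap times
#'
#' One-call orchestration of the three nonparametric estimators: the joint CDF
#' of the two gap types on `u1` \eqn{\times} `u2`, the marginal survival of
#' Type I gaps at all distinct uncensored Type I times, and (optionally) the
#' conditional CDF of Type II gaps given that the Type I gap falls in
#' `given_interval`. Standard errors and pointwise confidence intervals come
#' from a subject-level bootstrap (`n_boot` replicates, normal-quantile
#' intervals clipped to \eqn{[0, 1]}).
#'
#' @param table a validated [episode_table()].
#' @param level confidence level, between 0.50 and 0.99.
#' @param ai weight selector: 1 for unit weights \eqn{a(C_i) = 1}, 2 for
#'   \eqn{a(C_i) = C_i}.
#' @param u1,u2 grids for the joint CDF; default to the deciles of the
#'   observed uncensored Type I / Type II gaps.
#' @param conditional logical; also estimate the conditional CDF?
#' @param given_interval numeric pair `c(v1, v2)`, required when
#'   `conditional = TRUE`.
#' @param y_grid evaluation grid for the conditional CDF; defaults to the
#'   deciles of the observed uncensored Type II gaps.
#' @param n_boot bootstrap replicates (at least 2).
#' @param seed optional integer seed making the bootstrap reproducible.
#' @return An object of class `bivgap_np` with data-frame components
#'   `joint_cdf` (`x`, `y`, `cdf`, `se`, `ci_low`, `ci_high`),
#'   `marginal_survival` (`time`, `survival`, `se`, `ci_low`, `ci_high`) and,
#'   if requested, `conditional_cdf` (`y`, `cdf`, `se`, `ci_low`, `ci_high`),
#'   plus `tau_c_hat`, `level`, `ai` and `given_interval`.
#' @examples
#' tab <- sim_bivgap(sim_scenario(nsize = 40, seed = 1))
#' np <- bivgap_np(tab, n_boot = 25, seed = 2)
#' head(np)
#' @export
bivgap_np <- function(table, level = 0.95, ai = 1, u1 = NULL, u2 = NULL,
                      conditional = FALSE, given_interval = NULL,
                      y_grid = NULL, n_boot = 200, seed = NULL) {
  stopifnot(inherits(table, "episode_table"))
  if (level < 0.50 || level > 0.99)
    stop("`level` must be between 0.50 and 0.99", call. = FALSE)
  if (conditional && is.null(given_interval))
    stop("`given_interval` must be specified if `conditional = TRUE`",
         call. = FALSE)
  if (n_boot < 2) stop("`n_boot` must be at least 2", call. = FALSE)
  core <- np_core(table, ai)

  dec <- function(v) unique(unname(quantile(v, seq(0.1, 1, by = 0.1))))
  unc_x <- core$xs[core$d1 == 1]
  unc_y <- core$ys[core$d2 == 1]
  if (is.null(u1)) u1 <- dec(unc_x)
  if (is.null(u2)) u2 <- dec(unc_y)
  if (is.null(y_grid)) y_grid <- dec(unc_y)

  joint <- joint_cdf(core, u1, u2)
  marg <- marginal_survival(core)
  cond <- if (conditional)
    conditional_cdf(core, given_interval, y_grid) else NULL

  # subject-level bootstrap of all requested estimates on the fixed grids
  if (!is.null(seed)) set.seed(seed)
  arrays <- tab_arrays(table)
  bj <- matrix(NA_real_, n_boot, nrow(joint))
  bm <- matrix(NA_real_, n_boot, nrow(marg))
  bc <- if (conditional) matrix(NA_real_, n_boot, length(y_grid)) else NULL
  skipped <- 0L
  for (r in seq_len(n_boot)) {
    rc <- resample_core(arrays, ai)
    if (is.null(rc)) { skipped <- skipped + 1L; next }
    bj[r, ] <- joint_cdf_eval(rc, joint$x, joint$y)
    bm[r, ] <- attr(marginal_survival(rc), "sfun")(marg$time)
    if (conditional) {
      bc[r, ] <- tryCatch(
        conditional_cdf(rc, given_interval, y_grid)$cdf,
        error = function(e) rep(NA_real_, length(y_grid)))
    }
  }
  if (skipped > 0L)
    warning(sprintf("%d bootstrap replicates without uncensored episodes %s",
                    skipped, "were skipped"), call. = FALSE)

  zq <- qnorm(1 - (1 - level) / 2)
  add_ci <- function(df, est_col, boot, clip = TRUE) {
    df$se <- apply(boot, 2, sd, na.rm = TRUE)
    df$ci_low <- df[[est_col]] - zq * df$se
    df$ci_high <- df[[est_col]] + zq * df$se
    if (clip) {
      df$ci_low <- pmin(pmax(df$ci_low, 0), 1)
      df$ci_high <- pmin(pmax(df$ci_high, 0), 1)
    }
    df
  }
  joint <- add_ci(joint, "cdf", bj)
  joint$se[is.na(joint$cdf)] <- NA_real_
  marg <- add_ci(marg, "survival", bm)
  if (conditional) cond <- add_ci(cond, "cdf", bc)

  structure(list(
    joint_cdf = joint,
    marginal_survival = marg,
    conditional_cdf = cond,
    tau_c_hat = core$tau_c_hat,
    level = level, ai = ai,
    given_interval = if (conditional) given_interval else NULL,
    n_boot = n_boot
  ), class = "bivgap_np")
}

#' @export
print.bivgap_np <- function(x, ...) {
  cat(sprintf(
    "Nonparametric bivariate gap-time analysis (ai = %d, level = %g)\n",
    x$ai, x$level))
  cat(sprintf("tau_c_hat = %g\n\nJoint CDF:\n", x$tau_c_hat))
  print(x$joint_cdf)
  cat("\nMarginal survival (Type I gaps):\n")
  print(x$marginal_survival)
  if (!is.null(x$conditional_cdf)) {
    cat(sprintf("\nConditional CDF, Pr(Y <= y | %g <= X <= %g):\n",
                x$given_interval[1], x$given_interval[2]))
    print(x$conditional_cdf)
  }
  invisible(x)
}

#' @export
head.bivgap_np <- function(x, n = 6L, ...) {
  out <- list(joint_cdf = head(x$joint_cdf, n),
              marginal_survival = head(x$marginal_survival, n))
  if (!is.null(x$conditional_cdf))
    out$conditional_cdf <- head(x$conditional_cdf, n)
  out
}
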