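# Internal representation for regression: per-subject covariate matrix A and
# per-episode arrays. Episode arrays cover all episodes; estimating functions
# use the j <= m_i^* subset (flag `use`).
reg_core <- function(table, covariates = table$covariate_names) {
  stopifnot(inherits(table, "episode_table"))
  if (!length(covariates)) stop("no covariates specified", call. = FALSE)
  check_time_invariant_covariates(table, covariates)
  df <- table$data
  subj <- match(df$id, table$subjects)
  first <- !duplicated(subj)
  A <- as.matrix(df[first, covariates, drop = FALSE])
  storage.mode(A) <- "double"
  rownames(A) <- table$subjects
  m_star <- unname(table$m_star)
  list(
    n = table$n, p = ncol(A), A = A, covariates = covariates,
    subj = subj, epi = df$episode,
    X = df$xij, Y = df$yij, Z = df$zij, dX = df$d1, dY = df$d2,
    use = df$episode <= m_star[subj],
    m = unname(table$m), m_star = m_star, ci = unname(table$ci),
    rows_by_subj = split(seq_len(nrow(df)), subj)
  )
}

# subject bootstrap of a reg core (whole trajectories, with replacement)
reg_resample <- function(rc, pick = sample.int(rc$n, replace = TRUE)) {
  rows <- unlist(rc$rows_by_subj[pick], use.names = FALSE)
  subj <- rep(seq_along(pick), rc$m[pick])
  m_star <- rc$m_star[pick]
  list(
    n = rc$n, p = rc$p, A = rc$A[pick, , drop = FALSE],
    covariates = rc$covariates,
    subj = subj, epi = rc$epi[rows],
    X = rc$X[rows], Y = rc$Y[rows], Z = rc$Z[rows],
    dX = rc$dX[rows], dY = rc$dY[rows],
    use = rc$epi[rows] <= m_star[subj],
    m = rc$m[pick], m_star = m_star, ci = rc$ci[pick],
    rows_by_subj = split(seq_along(rows), subj)
  )
}

split_b <- function(b, p) {
  if (length(b) != 2 * p)
    stop(sprintf("coefficient vector must have length %d", 2 * p),
         call. = FALSE)
  list(b1 = b[seq_len(p)], b2 = b[p + seq_len(p)])
}

#' Rank-regression transformed gap times
#'
#' Computes the covariate-adjusted (transformed) gap times used by the
#' rank-based estimating functions: latent scale
#' \eqn{\tilde X^0_{ij}(b) = X_{ij} e^{-A_i' b_1}} and
#' \eqn{\tilde Z^0_{ij}(b) = X_{ij} e^{-A_i' b_1} + Y_{ij} e^{-A_i' b_2}},
#' with observed counterparts truncated at
#' \eqn{C_i e^{-A_i' b_1} - \sum_{l < j} \tilde Z_{il}(b)}, the transformed
#' residual follow-up. The censoring time \eqn{C_i} is reconstructed as the
#' subject's total observed follow-up.
#'
#' @param table a validated [episode_table()] with covariates.
#' @param b stacked coefficient vector `c(b1, b2)` of length `2p`.
#' @param covariates covariate names (default: all carried by the table).
#' @return data frame with columns `id`, `episode`, `xt` and `zt` (observed
#'   transformed times) and `xt0`, `zt0` (before truncation).
#' @export
chang_transform <- function(table, b, covariates = table$covariate_names) {
  rc <- if (inherits(table, "episode_table")) reg_core(table, covariates)
        else table
  tr <- chang_transform_core(rc, b)
  out <- data.frame(episode = rc$epi, xt = tr$Xt, zt = tr$Zt,
                    xt0 = tr$Xt0, zt0 = tr$Zt0)
  if (!is.null(rc$rows_by_subj)) out <- cbind(subject = rc$subj, out)
  out
}

chang_transform_core <- function(rc, b) {
  bb <- split_b(b, rc$p)
  s1 <- drop(rc$A %*% bb$b1)
  s2 <- drop(rc$A %*% bb$b2)
  e1 <- exp(-s1)[rc$subj]
  Xt0 <- rc$X * e1
  Zt0 <- rc$X * e1 + rc$Y * exp(-s2)[rc$subj]
  Cb <- (rc$ci * exp(-s1))[rc$subj]
  # sequential truncation Zt_j = min(Zt0_j, Cb - sum_{l<j} Zt_l) telescopes:
  # cum_j = min(cumsum(Zt0)_j, Cb), so it vectorizes within subject; the
  # cumsum runs per subject so that exact-equality boundaries (a censored
  # gap hitting the bound) are preserved bitwise
  S0 <- stats::ave(Zt0, rc$subj, FUN = cumsum)
  bound <- Cb - pmin(S0 - Zt0, Cb)          # residual transformed follow-up
  Zt <- pmin(Zt0, bound)
  Xt <- pmin(Xt0, bound)
  # completeness on the transformed scale: the transformed gap escaped the
  # truncation bound (a last-episode censored gap hits it exactly)
  list(Xt = Xt, Zt = Zt, Xt0 = Xt0, Zt0 = Zt0,
       deltaX = as.numeric(Xt0 < bound), deltaZ = as.numeric(Zt0 < bound))
}

#' Rank-based estimating functions for the AFT model
#'
#' Evaluates the pair of nonsmooth, rank-based estimating functions
#' \deqn{U_k(b) = n^{-1/2} \sum_i \frac{1}{m_i^*} \sum_{j \le m_i^*}
#'   \left[A_i - \frac{S_1\{b, t_{ij}(b)\}}{S_0\{b, t_{ij}(b)\}}\right],}
#' where for \eqn{U_1} the evaluation times are the transformed Type I gaps
#' \eqn{\tilde X_{ij}(b)} and for \eqn{U_2} the transformed total gaps
#' \eqn{\tilde Z_{ij}(b)}, and \eqn{S_0, S_1} are the weighted at-risk size
#' and covariate sum over the transformed times. A zero coefficient vector
#' leaves the times untransformed.
#'
#' @inheritParams chang_transform
#' @details The outer sums run over episodes that remain complete on the
#'   transformed scale (the transformed gap did not hit the transformed
#'   residual-follow-up bound); truncated transformed times still contribute
#'   to the at-risk sums \eqn{S_0, S_1}, exactly as censored observations
#'   enter Kaplan-Meier risk sets. Without this restriction the functions
#'   are not centered at the true coefficients, because the truncation bound
#'   depends on the covariates.
#' @return list with components `U1` and `U2`, each a `p`-vector.
#' @export
chang_U <- function(table, b, covariates = table$covariate_names) {
  rc <- if (inherits(table, "episode_table")) reg_core(table, covariates)
        else table
  tr <- chang_transform_core(rc, b)
  list(U1 = chang_U_one(rc, tr$Xt, tr$deltaX),
       U2 = chang_U_one(rc, tr$Zt, tr$deltaZ))
}

# one estimating function given transformed evaluation times and the
# transformed-scale completeness indicator; risk-set sums by sorted cumsum
chang_U_one <- function(rc, tvec, dvec) {
  use <- rc$use
  t_e <- tvec[use]
  d_e <- dvec[use]
  s_e <- rc$subj[use]
  wm <- 1 / rc$m_star[s_e]
  A_e <- rc$A[s_e, , drop = FALSE]
  o <- order(t_e, decreasing = TRUE)
  c0 <- cumsum(wm[o])
  c1 <- A_e[o, , drop = FALSE] * wm[o]
  for (k in seq_len(rc$p)) c1[, k] <- cumsum(c1[, k])
  # ties share the risk-set mass accumulated at the end of their run
  r <- rle(t_e[o])
  block_end <- rep(cumsum(r$lengths), r$lengths)
  S0 <- numeric(length(t_e)); S1 <- matrix(0, length(t_e), rc$p)
  S0[o] <- c0[block_end]
  S1[o, ] <- c1[block_end, , drop = FALSE]
  ratio <- S1 / S0
  ratio[S0 == 0, ] <- 0                          # empty risk set: term drops
  wd <- wm * d_e
  drop(crossprod(A_e - ratio, wd)) / sqrt(rc$n)
}

# per-subject contributions psi_i with U = n^{-1/2} sum_i psi_i; used to
# estimate the sampling covariance of U at the fit
chang_psi <- function(rc, tvec, dvec) {
  use <- rc$use
  t_e <- tvec[use]; d_e <- dvec[use]; s_e <- rc$subj[use]
  wm <- 1 / rc$m_star[s_e]
  A_e <- rc$A[s_e, , drop = FALSE]
  o <- order(t_e, decreasing = TRUE)
  c0 <- cumsum(wm[o])
  c1 <- A_e[o, , drop = FALSE] * wm[o]
  for (k in seq_len(rc$p)) c1[, k] <- cumsum(c1[, k])
  r <- rle(t_e[o])
  block_end <- rep(cumsum(r$lengths), r$lengths)
  S0 <- numeric(length(t_e)); S1 <- matrix(0, length(t_e), rc$p)
  S0[o] <- c0[block_end]
  S1[o, ] <- c1[block_end, , drop = FALSE]
  ratio <- S1 / S0
  ratio[S0 == 0, ] <- 0
  term <- (A_e - ratio) * (wm * d_e)
  psi <- matrix(0, rc$n, rc$p)
  rs <- rowsum(term, s_e)
  psi[as.integer(rownames(rs)), ] <- rs
  psi
}

# deterministic multistart set for the simplex search: the origin plus
# +/- 0.5 patterns (5 starts), shifted to `center` when given
chang_starts <- function(p, center = rep(0, p)) {
  base <- rbind(rep(0, p), rep(0.5, p), rep(-0.5, p),
                0.5 * (-1)^seq_len(p), 0.25 * (-1)^(seq_len(p) + 1))
  sweep(base, 2, center, "+")
}

# minimize ||U(b) - target||^2 over one p-dim block by simplex search
chang_minimize <- function(fn, p, max_iter, center = rep(0, p),
                           starts = chang_starts(p, center)) {
  best <- NULL
  for (s in seq_len(nrow(starts))) {
    res <- if (p == 1L) {
      o <- optimize(function(v) fn(v), interval = starts[s, 1] + c(-2, 2))
      list(par = o$minimum, value = o$objective)
    } else {
      o <- optim(starts[s, ], fn, method = "Nelder-Mead",
                 control = list(maxit = max_iter))
      list(par = o$par, value = o$value)
    }
    if (is.null(best) || res$value < best$value) best <- res
  }
  best
}

# coarse prescan for displaced solutions: the perturbed systems solved by the
# resampling variance can have roots several units from the fit
wide_starts <- function(fn, p, center, span = 4, step = 1, keep = 3) {
  grid <- if (p == 1L) {
    matrix(center + seq(-span, span, by = step), ncol = 1)
  } else if (p == 2L) {
    as.matrix(expand.grid(center[1] + seq(-span, span, by = step),
                          center[2] + seq(-span, span, by = step)))
  } else {
    sweep(matrix(runif(12 * p, -span / 2, span / 2), ncol = p), 2, center, "+")
  }
  vals <- apply(grid, 1, fn)
  rbind(grid[order(vals)[seq_len(min(keep, nrow(grid)))], , drop = FALSE],
        center)
}

chang_nonconv <- function() {
  stop("Error: Max Iterations reached. Did not converge.", call. = FALSE)
}

#' Solve the rank-based estimating equations
#'
#' Point estimation for the AFT model by the nonsmooth rank-based method:
#' minimizes \eqn{\|U_1(b_1)\|^2} and then \eqn{\|U_2(\hat b_1, b_2)\|^2} by
#' a derivative-free simplex search from five deterministic starting points
#' (the estimating functions are step functions of `b`, so derivative-based
#' solvers do not apply). The fit is declared converged when the attained
#' \eqn{\|U\|_\infty} falls below `tol`; otherwise the contractual error
#' `"Error: Max Iterations reached. Did not converge."` is raised. A
#' covariate without variation across subjects admits no root and raises the
#' same error.
#'
#' @inheritParams chang_transform
#' @param max_iter iteration cap for each simplex search.
#' @param tol convergence tolerance on \eqn{\|U\|_\infty} at the minimiser.
#'   The estimating functions are step functions, so an exact root rarely
#'   exists; the attainable minimum is set by the step granularity, and at
#'   the root the \eqn{\sqrt n}-scaled functions have unit-order sampling
#'   scale. The default 1 accepts any attained crossing while still
#'   catching degenerate systems, whose residuals are far larger.
#' @return list with `beta1`, `beta2`, `U` (residual value of the stacked
#'   estimating functions), `residual_norm` and `converged`.
#' @export
solve_chang <- function(table, covariates = table$covariate_names,
                        max_iter = 1000, tol = 1) {
  rc <- if (inherits(table, "episode_table")) reg_core(table, covariates)
        else table
  if (any(apply(rc$A, 2, var) == 0)) chang_nonconv()
  if (max_iter <= 0) chang_nonconv()
  p <- rc$p
  # inductive block solves, iterated twice: U1 also depends on b2 through the
  # transformed truncation bound, so a second pass makes the joint residual
  # coherent
  b1 <- rep(0, p); b2 <- rep(0, p)
  for (pass in 1:2) {
    f1 <- function(v) {
      tr <- chang_transform_core(rc, c(v, b2))
      sum(chang_U_one(rc, tr$Xt, tr$deltaX)^2)
    }
    b1 <- chang_minimize(f1, p, max_iter, center = b1)$par
    f2 <- function(v) {
      tr <- chang_transform_core(rc, c(b1, v))
      sum(chang_U_one(rc, tr$Zt, tr$deltaZ)^2)
    }
    b2 <- chang_minimize(f2, p, max_iter, center = b2)$par
  }
  U <- chang_U(rc, c(b1, b2))
  resid <- max(abs(c(U$U1, U$U2)))
  if (!is.finite(resid) || resid > tol) chang_nonconv()
  list(beta1 = b1, beta2 = b2, U = U, residual_norm = resid,
       converged = TRUE)
}

#' Resampling covariance for the rank-based estimates
#'
#' Perturbed-estimating-equation resampling: for each replicate a normal
#' vector \eqn{Z_r \sim N(0, \hat\Omega)} of length `2p` is drawn, where
#' \eqn{\hat\Omega} estimates the sampling covariance of the
#' \eqn{\sqrt n}-scaled estimating functions at the fit from per-subject
#' contributions, and the displaced system
#' \eqn{U_1(b_1) = Z_{r,1}}, \eqn{U_2(b_1^{(r)}, b_2) = Z_{r,2}} is solved by
#' the same simplex search as the point estimate, started at the fitted
#' coefficients. The covariance matrix of the replicate solutions estimates
#' the sampling covariance of the coefficient estimates (the estimating
#' functions carry the \eqn{n^{1/2}} scaling internally).
#'
#' @inheritParams solve_chang
#' @param fit result of [solve_chang()].
#' @param n_resample number of replicates (at least 2).
#' @param seed optional integer seed.
#' @return `2p x 2p` covariance matrix. If more than 20\% of the replicate
#'   systems fail to solve, an error advises the smooth U-statistic method.
#' @export
parzen_resample_vcov <- function(table, fit,
                                 covariates = table$covariate_names,
                                 n_resample = 200, max_iter = 1000,
                                 tol = 1, seed = NULL) {
  rc <- if (inherits(table, "episode_table")) reg_core(table, covariates)
        else table
  if (n_resample < 2)
    stop("`n_resample` must be at least 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  p <- rc$p
  # perturbations are drawn from the estimated law of U at the root,
  # N(0, Omega-hat), with Omega-hat built from per-subject contributions;
  # unit-variance draws would routinely overshoot the attainable range of
  # the step-function estimating equations
  tr0 <- chang_transform_core(rc, c(fit$beta1, fit$beta2))
  psi <- cbind(chang_psi(rc, tr0$Xt, tr0$deltaX),
               chang_psi(rc, tr0$Zt, tr0$deltaZ))
  psi <- sweep(psi, 2, colMeans(psi))
  Omega <- crossprod(psi) / rc$n
  eg <- eigen(Omega, symmetric = TRUE)
  Ohalf <- eg$vectors %*% diag(sqrt(pmax(eg$values, 0)), 2 * p)
  sols <- matrix(NA_real_, n_resample, 2 * p)
  failed <- 0L
  for (r in seq_len(n_resample)) {
    zr <- drop(Ohalf %*% rnorm(2 * p))
    b1 <- fit$beta1; b2 <- fit$beta2
    for (pass in 1:2) {
      f1 <- function(v) {
        tr <- chang_transform_core(rc, c(v, b2))
        sum((chang_U_one(rc, tr$Xt, tr$deltaX) - zr[seq_len(p)])^2)
      }
      b1 <- chang_minimize(f1, p, max_iter, starts = if (pass == 1)
        wide_starts(f1, p, b1) else matrix(b1, nrow = 1))$par
      f2 <- function(v) {
        tr <- chang_transform_core(rc, c(b1, v))
        sum((chang_U_one(rc, tr$Zt, tr$deltaZ) - zr[p + seq_len(p)])^2)
      }
      b2 <- chang_minimize(f2, p, max_iter, starts = if (pass == 1)
        wide_starts(f2, p, b2) else matrix(b2, nrow = 1))$par
    }
    U <- chang_U(rc, c(b1, b2))
    ok <- max(abs(c(U$U1 - zr[seq_len(p)], U$U2 - zr[p + seq_len(p)]))) <= tol
    if (ok) sols[r, ] <- c(b1, b2) else failed <- failed + 1L
  }
  if (failed > 0.2 * n_resample)
    stop(sprintf(paste(
      "%d of %d resampling replicates did not converge;",
      "consider method = 'lee' instead"), failed, n_resample), call. = FALSE)
  V <- cov(sols[stats::complete.cases(sols), , drop = FALSE])
  (V + t(V)) / 2
}

#' Kaplan-Meier estimate of the censoring survival
#'
#' Estimates the survival function \eqn{G(\cdot)} of the censoring time by
#' treating censoring as the event in first-episode data: `which = 1` uses
#' the first-episode Type I gaps with indicator \eqn{1 - \Delta^X_{i1}};
#' `which = 2` uses the first-episode total gaps with \eqn{1 - \Delta^Y_{i1}}.
#' The evaluation bound `L` defaults to the largest *uncensored*
#' first-episode time on the matching scale (Type I gaps for `which = 1`,
#' total gaps for `which = 2`), which guarantees the inverse weights
#' \eqn{\hat G(t \wedge L)} stay positive: the estimate can only reach zero
#' beyond the largest observation when that observation is a censoring
#' event, and the bound sits strictly below it. Evaluations that would still
#' hit zero (exact ties) are floored at the smallest positive estimate with
#' a warning.
#'
#' @param table a validated [episode_table()].
#' @param which 1 or 2 (see above).
#' @param L evaluation bound; `NULL` for the default rule.
#' @return object of class `censoring_km`: `times`, `surv`, right-continuous
#'   evaluator `G(t)`, `Gmin` (`G(t %min% L)`, floored), `L`, `which`.
#' @export
censoring_km <- function(table, which = 1, L = NULL) {
  stopifnot(inherits(table, "episode_table"), which %in% c(1, 2))
  df <- table$data
  first <- df[df$episode == 1L, , drop = FALSE]
  if (which == 1) {
    time <- first$xij; event <- 1 - first$d1
    unc <- first$xij[first$d1 == 1]
  } else {
    time <- first$zij; event <- 1 - first$d2
    unc <- first$zij[first$d2 == 1]
  }
  if (is.null(L)) L <- if (length(unc)) max(unc) else max(time)
  if (all(event == 0)) {
    message("no censoring events in episode 1; G-hat is identically 1")
    G <- function(t) rep(1, length(t))
    times <- sort(unique(time)); surv <- rep(1, length(times))
  } else {
    km <- survfit(Surv(time, event) ~ 1)
    times <- km$time
    surv <- km$surv
    G <- stepfun(times, c(1, surv), right = FALSE)
  }
  Gmin <- function(t) {
    g <- G(pmin(t, L))
    if (any(g <= 0)) {
      floor_val <- min(surv[surv > 0], 1)
      warning("G-hat reached zero inside the evaluation bound; ",
              "flooring at the smallest positive value", call. = FALSE)
      g[g <= 0] <- floor_val
    }
    g
  }
  structure(list(times = times, surv = surv, G = G, Gmin = Gmin,
                 L = L, which = which),
            class = "censoring_km")
}

#' @export
print.censoring_km <- function(x, ...) {
  cat(sprintf(
    "Censoring-time Kaplan-Meier (which = %d), L = %g, %d support times\n",
    x$which, x$L, length(x$times)))
  invisible(x)
}

#' Bounded log-scale comparison kernel
#'
#' The smooth, symmetric kernel used by the U-statistic estimating equations:
#' \deqn{O_L(s, t) = \log[\min\{\max(t, s), L\}] - \log(L).}
#' It is nonpositive, equals 0 when both arguments reach the bound `L`, and
#' is monotone in each argument with the other fixed.
#'
#' @param s,t positive times (vectorized with recycling).
#' @param L positive bound.
#' @return numeric vector of kernel values.
#' @examples
#' o_kernel(10, 10, 10)   # 0
#' o_kernel(1, 2, 10)     # log(2) - log(10)
#' @export
o_kernel <- function(s, t, L) {
  if (any(s <= 0) || any(t <= 0) || any(L <= 0))
    stop("o_kernel requires positive arguments", call. = FALSE)
  log(pmin(pmax(t, s), L)) - log(L)
}

#' Smooth U-statistic estimating functions
#'
#' Evaluates the pair of smooth estimating functions built from all ordered
#' subject pairs \eqn{(i, i')} with covariate contrasts
#' \eqn{A_{ii'} = A_{i'} - A_i}:
#' \deqn{D_1^*(b_1) = n^{-2} \sum_i \sum_{i'} A_{ii'} \frac{1}{m_i^*}
#'   \sum_{j \le m_i^*} \frac{\Delta^X_{ij}\,
#'   O_L\{X_{ij}, X_{ii'j}(b_1)\}}{\hat G_1(X_{ij} \wedge L)},}
#' and its Type II analogue \eqn{D_2^*(b)} with pairwise-transformed total
#' gaps \eqn{Z_{ii'j}(b) = e^{A_{ii'}'b_1} X_{ij} + e^{A_{ii'}'b_2} Y_{ij}},
#' indicator \eqn{\Delta^Y_{ij}} and inverse weight \eqn{\hat G_2}. The
#' kernel is [o_kernel()] with a common bound `L`.
#'
#' @inheritParams chang_transform
#' @param km1,km2 [censoring_km()] objects for the two inverse weights;
#'   computed from `table` when `NULL`.
#' @return list with `D1` and `D2`, each a `p`-vector.
#' @export
lee_D <- function(table, b, covariates = table$covariate_names,
                  km1 = NULL, km2 = NULL) {
  rc <- if (inherits(table, "episode_table")) reg_core(table, covariates)
        else table
  if (inherits(table, "episode_table")) {
    if (is.null(km1)) km1 <- censoring_km(table, 1)
    if (is.null(km2)) km2 <- censoring_km(table, 2)
  }
  if (is.null(km1) || is.null(km2))
    stop("km1 and km2 must be supplied when `table` is a core", call. = FALSE)
  if (all(apply(rc$A, 2, var) == 0))
    stop("no covariate variation", call. = FALSE)
  bb <- split_b(b, rc$p)
  list(D1 = lee_D1(rc, bb$b1, km1), D2 = lee_D2(rc, bb$b1, bb$b2, km2))
}

# D1*: rows are episodes with positive weight, columns are partners i'
lee_D1 <- function(rc, b1, km1) {
  use <- rc$use & rc$dX == 1
  s_e <- rc$subj[use]
  X_e <- rc$X[use]
  L <- km1$L
  w_e <- 1 / (rc$m_star[s_e] * km1$Gmin(X_e))
  s1 <- drop(rc$A %*% b1)
  Tmat <- outer(X_e * exp(-s1[s_e]), exp(s1))      # X_{ii'j}(b1), E x n
  K <- log(pmin(pmax(Tmat, X_e), L)) - log(L)
  lee_contract(rc, K, w_e, s_e)
}

lee_D2 <- function(rc, b1, b2, km2) {
  use <- rc$use & rc$dY == 1
  s_e <- rc$subj[use]
  Z_e <- rc$Z[use]
  L <- km2$L
  w_e <- 1 / (rc$m_star[s_e] * km2$Gmin(Z_e))
  s1 <- drop(rc$A %*% b1)
  s2 <- drop(rc$A %*% b2)
  Tmat <- outer(rc$X[use] * exp(-s1[s_e]), exp(s1)) +
    outer(rc$Y[use] * exp(-s2[s_e]), exp(s2))      # Z_{ii'j}(b), E x n
  K <- log(pmin(pmax(Tmat, Z_e), L)) - log(L)
  lee_contract(rc, K, w_e, s_e)
}

# contract sum_e w_e sum_{i'} (A_{i'} - A_{s_e}) K[e, i'] into a p-vector
lee_contract <- function(rc, K, w_e, s_e) {
  q <- colSums(w_e * K)                            # length n
  r <- rowSums(K)                                  # length E
  term1 <- drop(crossprod(rc$A, q))
  term2 <- drop(crossprod(rc$A[s_e, , drop = FALSE], w_e * r))
  (term1 - term2) / rc$n^2
}

# damped Newton with central-difference Jacobian; the estimating functions
# are smooth and componentwise monotone, so this converges rapidly
newton_solve <- function(fn, b0, tol = 1e-8, max_iter = 100) {
  b <- b0
  D <- fn(b)
  for (it in seq_len(max_iter)) {
    if (max(abs(D)) < tol)
      return(list(par = b, value = D, converged = TRUE, iter = it - 1L))
    J <- num_jacobian(fn, b)
    step <- tryCatch(-solve(J, D),
                     error = function(e) -D / max(abs(diag(J)), 1e-8))
    lambda <- 1
    for (h in 1:30) {
      Dn <- fn(b + lambda * step)
      if (sqrt(sum(Dn^2)) < sqrt(sum(D^2)) * (1 - 1e-4 * lambda)) break
      lambda <- lambda / 2
    }
    b <- b + lambda * step
    D <- Dn
  }
  list(par = b, value = D, converged = max(abs(D)) < tol, iter = max_iter)
}

num_jacobian <- function(fn, b, h = 1e-5) {
  p <- length(b)
  f0 <- fn(b)
  J <- matrix(0, length(f0), p)
  for (k in seq_len(p)) {
    hk <- h * max(1, abs(b[k]))
    bp <- b; bp[k] <- b[k] + hk
    bm <- b; bm[k] <- b[k] - hk
    J[, k] <- (fn(bp) - fn(bm)) / (2 * hk)
  }
  J
}

#' Solve the smooth U-statistic estimating equations
#'
#' Point estimation for the AFT model by the smooth method: first solves
#' \eqn{D_1^*(b_1) = 0}, then \eqn{D_2^*((\hat\beta_1', b_2')') = 0} with
#' \eqn{b_1} fixed at the stage-one solution, by damped Newton iteration with
#' a central-difference Jacobian. The smooth, monotone estimating functions
#' admit a unique root, so nonconvergence is rare; if the iteration cap is
#' reached the contractual error
#' `"Error: Max Iterations reached. Did not converge."` is raised.
#'
#' @inheritParams lee_D
#' @param max_iter Newton iteration cap per stage.
#' @param tol residual tolerance on \eqn{\|D\|_\infty}.
#' @return list with `beta1`, `beta2`, `residual_norm`, `converged`, and the
#'   censoring estimators `km1`, `km2` used.
#' @export
solve_lee <- function(table, covariates = table$covariate_names,
                      max_iter = 100, tol = 1e-8, km1 = NULL, km2 = NULL) {
  rc <- if (inherits(table, "episode_table")) reg_core(table, covariates)
        else table
  if (inherits(table, "episode_table")) {
    if (is.null(km1)) km1 <- censoring_km(table, 1)
    if (is.null(km2)) km2 <- censoring_km(table, 2)
  }
  if (any(apply(rc$A, 2, var) == 0))
    stop("no covariate variation", call. = FALSE)
  if (max_iter <= 0) chang_nonconv()
  p <- rc$p
  s1 <- newton_solve(function(b1) lee_D1(rc, b1, km1), rep(0, p),
                     tol = tol, max_iter = max_iter)
  if (!s1$converged) chang_nonconv()
  s2 <- newton_solve(function(b2) lee_D2(rc, s1$par, b2, km2), rep(0, p),
                     tol = tol, max_iter = max_iter)
  if (!s2$converged) chang_nonconv()
  list(beta1 = s1$par, beta2 = s2$par,
       residual_norm = max(abs(c(s1$value, s2$value))),
       converged = TRUE, km1 = km1, km2 = km2)
}

#' Sandwich covariance for the smooth-method estimates
#'
#' Hybrid sandwich estimator
#' \eqn{\hat\Sigma^{-1} \hat\Omega (\hat\Sigma^{-1})'}: \eqn{\hat\Sigma} is
#' the central-difference Jacobian of the stacked estimating functions
#' \eqn{(D_1^{*\prime}, D_2^{*\prime})'} at the fitted coefficients (block
#' lower-triangular, since \eqn{D_1^*} does not involve \eqn{b_2}), and
#' \eqn{\hat\Omega} is the subject-level bootstrap covariance of the stacked
#' estimating functions evaluated at the fit, with the censoring
#' Kaplan-Meier estimators recomputed on each replicate (the evaluation
#' bound `L` stays fixed, as part of the functional's definition).
#'
#' @inheritParams solve_lee
#' @param fit result of [solve_lee()].
#' @param n_boot bootstrap replicates (at least 2).
#' @param seed optional integer seed.
#' @return `2p x 2p` symmetric positive semidefinite covariance matrix.
#' @export
lee_vcov <- function(table, fit, covariates = table$covariate_names,
                     n_boot = 200, seed = NULL) {
  stopifnot(inherits(table, "episode_table"))
  rc <- reg_core(table, covariates)
  p <- rc$p
  beta <- c(fit$beta1, fit$beta2)
  km1 <- fit$km1; km2 <- fit$km2
  stacked <- function(b, core, k1, k2) {
    bb <- split_b(b, p)
    c(lee_D1(core, bb$b1, k1), lee_D2(core, bb$b1, bb$b2, k2))
  }
  Sig <- num_jacobian(function(b) stacked(b, rc, km1, km2), beta)
  rc_cond <- rcond(Sig)
  if (!is.finite(rc_cond) || rc_cond < 1e-12)
    stop(sprintf(
      "singular Jacobian of the estimating functions (rcond = %.3g)",
      rc_cond), call. = FALSE)

  if (!is.null(seed)) set.seed(seed)
  reps <- matrix(NA_real_, n_boot, 2 * p)
  for (r in seq_len(n_boot)) {
    for (attempt in 1:10) {
      rb <- reg_resample(rc)
      if (!any(rb$dY[rb$use] == 1)) next
      ftab <- list(x1 = rb$X[rb$epi == 1L], z1 = rb$Z[rb$epi == 1L],
                   d1 = rb$dX[rb$epi == 1L], d2 = rb$dY[rb$epi == 1L])
      k1 <- km_from_vectors(ftab$x1, 1 - ftab$d1, km1$L, 1)
      k2 <- km_from_vectors(ftab$z1, 1 - ftab$d2, km2$L, 2)
      reps[r, ] <- suppressWarnings(stacked(beta, rb, k1, k2))
      break
    }
  }
  ok <- stats::complete.cases(reps)
  if (sum(ok) < 2)
    stop("bootstrap for the covariance produced fewer than 2 usable replicates",
         call. = FALSE)
  Omega <- cov(reps[ok, , drop = FALSE])
  Si <- solve(Sig)
  V <- Si %*% Omega %*% t(Si)
  (V + t(V)) / 2
}

# bare KM constructor used inside the bootstrap (no episode_table rebuild)
km_from_vectors <- function(time, event, L, which) {
  if (all(event == 0)) {
    G <- function(t) rep(1, length(t))
    surv <- 1
  } else {
    km <- survfit(Surv(time, event) ~ 1)
    G <- stepfun(km$time, c(1, km$surv), right = FALSE)
    surv <- km$surv
  }
  Gmin <- function(t) {
    g <- G(pmin(t, L))
    g[g <= 0] <- min(surv[surv > 0], 1)
    g
  }
  structure(list(G = G, Gmin = Gmin, L = L, which = which),
            class = "censoring_km")
}
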