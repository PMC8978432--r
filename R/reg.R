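#' Fit the accelerated failure time model for both gap types
#'
#' Regression of covariate effects on the log Type I and log Type II gap
#' times under the semiparametric AFT model
#' \deqn{\log X^0_{ij} = \gamma_{i1} + A_i'\beta_1 + \varepsilon_{ij1}, \quad
#'       \log Y^0_{ij} = \gamma_{i2} + A_i'\beta_2 + \varepsilon_{ij2},}
#' where the subject frailties \eqn{\gamma_i} and errors come from
#' unspecified distributions. Two estimation methods are available:
#' `"lee"` (default), the smooth U-statistic estimating equations solved by
#' Newton iteration with a hybrid sandwich covariance ([solve_lee()],
#' [lee_vcov()]); and `"chang"`, the nonsmooth rank-based equations solved by
#' simplex search with perturbed-equation resampling covariance
#' ([solve_chang()], [parzen_resample_vcov()]).
#'
#' @param table a validated [episode_table()] with covariates.
#' @param covariates covariate names to include (default: all carried by the
#'   table).
#' @param method `"lee"` or `"chang"`.
#' @param level confidence level for the Wald intervals.
#' @param max_iter,tol solver controls; `NULL` uses the method's default
#'   (see [solve_lee()] and [solve_chang()]).
#' @param n_resample replicates for the covariance estimate (bootstrap for
#'   `"lee"`, perturbed resampling for `"chang"`).
#' @param seed optional integer seed for the resampling.
#' @param se logical; compute the covariance matrix (default `TRUE`).
#' @return An object of class `bivgap_reg` with coefficient estimates for
#'   both gap types (named `"xij <cov>"` and `"yij <cov>"`), the covariance
#'   matrix, standard errors, Wald `z`, two-sided normal p-values and
#'   confidence limits, plus convergence diagnostics.
#' @examples
#' tab <- sim_bivgap(sim_scenario(nsize = 60, seed = 4))
#' fit <- bivgap_reg(tab, n_resample = 30, seed = 1)
#' summary(fit)
#' @export
bivgap_reg <- function(table, covariates = table$covariate_names,
                       method = c("lee", "chang"), level = 0.95,
                       max_iter = NULL, tol = NULL, n_resample = 200,
                       seed = NULL, se = TRUE) {
  stopifnot(inherits(table, "episode_table"))
  method <- match.arg(method)
  if (level < 0.50 || level > 0.99)
    stop("`level` must be between 0.50 and 0.99", call. = FALSE)
  p <- length(covariates)
  if (p < 1) stop("at least one covariate is required", call. = FALSE)

  if (method == "lee") {
    if (is.null(max_iter)) max_iter <- 100
    if (is.null(tol)) tol <- 1e-8
    sol <- solve_lee(table, covariates, max_iter = max_iter, tol = tol)
    V <- if (se) lee_vcov(table, sol, covariates,
                          n_boot = n_resample, seed = seed) else NULL
  } else {
    if (is.null(max_iter)) max_iter <- 1000
    if (is.null(tol)) tol <- 0.5
    sol <- solve_chang(table, covariates, max_iter = max_iter, tol = tol)
    V <- if (se) parzen_resample_vcov(table, sol, covariates,
                                      n_resample = n_resample,
                                      max_iter = max_iter, tol = tol,
                                      seed = seed) else NULL
  }

  nm <- c(paste("xij", covariates), paste("yij", covariates))
  est <- setNames(c(sol$beta1, sol$beta2), nm)
  out <- list(
    coefficients = est,
    beta1 = setNames(sol$beta1, covariates),
    beta2 = setNames(sol$beta2, covariates),
    vcov = V, method = method, level = level,
    converged = sol$converged,
    residual_norm = sol$residual_norm,
    n_used = table$n, covariates = covariates
  )
  if (!is.null(V)) {
    dimnames(out$vcov) <- list(nm, nm)
    out$se <- setNames(sqrt(pmax(diag(V), 0)), nm)
    zq <- qnorm(1 - (1 - level) / 2)
    out$z <- est / out$se
    out$p_value <- 2 * pnorm(-abs(out$z))
    out$ci_low <- est - zq * out$se
    out$ci_high <- est + zq * out$se
  }
  structure(out, class = "bivgap_reg")
}

require_converged <- function(fit) {
  if (!isTRUE(fit$converged))
    stop("the model fit did not converge; estimates are not available",
         call. = FALSE)
  invisible(fit)
}

#' @export
coef.bivgap_reg <- function(object, ...) {
  require_converged(object)
  object$coefficients
}

#' @export
vcov.bivgap_reg <- function(object, ...) {
  require_converged(object)
  if (is.null(object$vcov))
    stop("fit was computed without a covariance matrix (se = FALSE)",
         call. = FALSE)
  object$vcov
}

#' @export
confint.bivgap_reg <- function(object, parm, level = 0.95, ...) {
  require_converged(object)
  est <- object$coefficients
  se <- object$se
  if (is.null(se)) stop("fit has no standard errors", call. = FALSE)
  if (missing(parm)) parm <- names(est)
  bad <- setdiff(parm, names(est))
  if (length(bad))
    stop(sprintf("unknown parameter(s) %s; valid names are: %s",
                 paste(sQuote(bad), collapse = ", "),
                 paste(sQuote(names(est)), collapse = ", ")),
         call. = FALSE)
  zq <- qnorm(1 - (1 - level) / 2)
  out <- cbind(est[parm] - zq * se[parm], est[parm] + zq * se[parm])
  colnames(out) <- sprintf("%.1f %%", 100 * c((1 - level) / 2,
                                              1 - (1 - level) / 2))
  out
}

#' @export
summary.bivgap_reg <- function(object, level = object$level, ...) {
  require_converged(object)
  est <- object$coefficients
  tab <- if (is.null(object$se)) {
    data.frame(estimate = est, `exp(estimate)` = exp(est),
               check.names = FALSE)
  } else {
    zq <- qnorm(1 - (1 - level) / 2)
    z <- est / object$se
    data.frame(
      estimate = est, se = object$se, z = z,
      `p-value` = 2 * pnorm(-abs(z)),
      ci_low = est - zq * object$se, ci_high = est + zq * object$se,
      `exp(estimate)` = exp(est), check.names = FALSE)
  }
  structure(list(table = tab, method = object$method, level = level,
                 n_used = object$n_used,
                 residual_norm = object$residual_norm),
            class = "summary.bivgap_reg")
}

#' @export
print.summary.bivgap_reg <- function(x, ...) {
  cat(sprintf("AFT model for bivariate alternating gap times (method: %s)\n",
              x$method))
  cat(sprintf("n = %d subjects; residual norm %.3g; level %g\n\n",
              x$n_used, x$residual_norm, x$level))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
print.bivgap_reg <- function(x, ...) {
  print(summary(x))
  invisible(x)
}

#' Export a fitted AFT model
#'
#' Writes the coefficient table (and covariance matrix, for JSON) to disk.
#'
#' @param fit a [bivgap_reg()] object.
#' @param file output path.
#' @param format `"csv"` (coefficient table) or `"json"` (coefficients plus
#'   covariance matrix).
#' @return the file path, invisibly.
#' @export
write_fit <- function(fit, file, format = c("csv", "json")) {
  format <- match.arg(format)
  tab <- summary(fit)$table
  if (format == "csv") {
    write.csv(cbind(term = rownames(tab), tab), file, row.names = FALSE)
  } else {
    payload <- list(method = fit$method, level = fit$level,
                    coefficients = as.list(fit$coefficients),
                    se = as.list(fit$se), vcov = fit$vcov)
    jsonlite::write_json(payload, file, auto_unbox = TRUE, digits = NA,
                         matrix = "rowmajor")
  }
  invisible(file)
}
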