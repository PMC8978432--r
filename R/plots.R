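#' Event-history plot of alternating gap times
#'
#' Draws one horizontal bar per subject, with alternating segments for the
#' Type I and Type II gaps of each episode, subjects sorted by total
#' follow-up (ascending, bottom to top). With `by`, one panelled plot is
#' produced per qualifying categorical covariate (covariates are panelled
#' separately, never crossed); a covariate that looks continuous -- numeric
#' with more than six distinct values -- or categorical with more than six
#' levels is automatically dropped with a message.
#'
#' @param table a validated [episode_table()].
#' @param by optional character vector of covariate names to stratify by.
#' @param type_labels labels for the two gap types in the legend.
#' @return a `ggplot` object, or a named list of them when more than one
#'   `by` covariate qualifies.
#' @export
plot_events <- function(table, by = NULL,
                        type_labels = c("Type I", "Type II")) {
  stopifnot(inherits(table, "episode_table"))
  df <- table$data
  seg <- do.call(rbind, lapply(seq_len(table$n), function(i) {
    rows <- df[df$id == table$subjects[i], , drop = FALSE]
    starts <- cumsum(c(0, head(rows$zij, -1)))
    data.frame(
      id = rows$id[1],
      start = c(starts, starts + rows$xij),
      end = c(starts + rows$xij, starts + rows$zij),
      type = rep(type_labels, each = nrow(rows)),
      total = unname(table$ci[i]), row.names = NULL)
  }))
  seg <- seg[seg$end > seg$start, , drop = FALSE]
  ord <- names(sort(table$ci))
  seg$id <- factor(seg$id, levels = ord)

  base_plot <- function(d) {
    ggplot2::ggplot(d, ggplot2::aes(y = .data$id)) +
      ggplot2::geom_segment(
        ggplot2::aes(x = .data$start, xend = .data$end,
                     yend = .data$id, colour = .data$type),
        linewidth = 1.6) +
      ggplot2::scale_colour_manual(values = c("#d7301f", "#2b8cbe")) +
      ggplot2::labs(x = "Time since entry", y = "Subject", colour = "Gap") +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
  }
  if (is.null(by)) return(base_plot(seg))

  keep <- character(0)
  for (cv in by) {
    v <- df[[cv]]
    if (is.null(v)) {
      message(sprintf("covariate '%s' not found; dropped", cv)); next
    }
    if (is.numeric(v) && length(unique(v)) > 6) {
      message(sprintf(
        "'%s' is possibly a continuous variable and is automatically dropped",
        cv)); next
    }
    if (length(unique(v)) > 6) {
      message(sprintf("'%s' has more than 6 levels; dropped", cv)); next
    }
    keep <- c(keep, cv)
  }
  if (!length(keep)) return(base_plot(seg))
  lev <- df[!duplicated(df$id), c("id", keep), drop = FALSE]
  plots <- lapply(keep, function(cv) {
    d <- merge(seg, lev[, c("id", cv)], by = "id", sort = FALSE)
    d$id <- factor(d$id, levels = ord)
    names(d)[names(d) == cv] <- ".by"
    base_plot(d) + ggplot2::facet_wrap(~.by, scales = "free_y",
                                       labeller = ggplot2::label_both)
  })
  names(plots) <- keep
  if (length(plots) == 1L) plots[[1L]] else plots
}

#' Plot nonparametric estimates
#'
#' `plot_joint()` draws the contour of the estimated joint CDF, restricted
#' to the half-plane \eqn{x + y \le \hat\tau_c} (cells flagged `NA` are left
#' blank). `plot_marginal()` and `plot_conditional()` draw the marginal
#' survival of Type I gaps and the conditional CDF of Type II gaps as step
#' curves with the pointwise confidence band at the object's level. The
#' `plot()` method on a [bivgap_np()] object draws all available panels.
#'
#' @param np a [bivgap_np()] result.
#' @return a `ggplot` object.
#' @export
plot_joint <- function(np) {
  stopifnot(inherits(np, "bivgap_np"))
  d <- np$joint_cdf[!is.na(np$joint_cdf$cdf), , drop = FALSE]
  if (!nrow(d)) stop("joint CDF grid is empty", call. = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, z = .data$cdf)) +
    ggplot2::geom_contour_filled(bins = 10) +
    ggplot2::labs(x = "Type I gap time", y = "Type II gap time",
                  fill = "Joint CDF",
                  title = sprintf("Joint CDF (x + y <= %.3g)",
                                  np$tau_c_hat)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_joint
#' @export
plot_marginal <- function(np) {
  stopifnot(inherits(np, "bivgap_np"))
  d <- np$marginal_survival
  if (!nrow(d)) stop("marginal survival estimate is empty", call. = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(.data$time, .data$survival)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "Type I gap time", y = "Survival probability",
                  title = sprintf("Marginal survival (%d%% CI)",
                                  round(100 * np$level))) +
    ggplot2::theme_minimal()
}

#' @rdname plot_joint
#' @export
plot_conditional <- function(np) {
  stopifnot(inherits(np, "bivgap_np"))
  d <- np$conditional_cdf
  if (is.null(d) || !nrow(d))
    stop("no conditional CDF estimate in this object", call. = FALSE)
  ggplot2::ggplot(d, ggplot2::aes(.data$y, .data$cdf)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                      ymax = .data$ci_high),
                         fill = "grey80") +
    ggplot2::geom_step() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(
      x = "Type II gap time", y = "Conditional CDF",
      title = sprintf("Pr(Y <= y | %g <= X <= %g), %d%% CI",
                      np$given_interval[1], np$given_interval[2],
                      round(100 * np$level))) +
    ggplot2::theme_minimal()
}

#' @export
plot.bivgap_np <- function(x, ...) {
  plots <- list(joint = plot_joint(x), marginal = plot_marginal(x))
  if (!is.null(x$conditional_cdf)) plots$conditional <- plot_conditional(x)
  for (p in plots) print(p)
  invisible(plots)
}

#' @importFrom ggplot2 .data
NULL
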