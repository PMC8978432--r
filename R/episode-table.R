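#' Build a validated episode table for bivariate alternating recurrent events
#'
#' Constructs the data object used by every estimator in the package from a
#' long-format data frame with one row per episode (one Type I gap followed by
#' one Type II gap) per subject. Rows are sorted by subject and episode number;
#' subjects with a missing value in any required column or requested covariate
#' are dropped in full, with a message reporting how many subjects remain.
#'
#' The observed-data structure is: subject \eqn{i} contributes \eqn{m_i}
#' episodes; episodes \eqn{j < m_i} are fully observed (\code{d1 = d2 = 1}),
#' while in the last episode the Type II gap is always censored
#' (\code{d2 = 0}) and the Type I gap may be. The effective episode count
#' \eqn{m_i^*} equals \eqn{m_i - 1} when \eqn{m_i \ge 2} and 1 otherwise; it
#' weights all risk and jump sums to offset the informative number of episodes
#' per subject.
#'
#' @param data data frame in long format.
#' @param id,episode,xij,yij,d1,d2 column names (strings) mapping the required
#'   variables: subject identifier, episode number, Type I gap length, Type II
#'   gap length and their censoring indicators (1 = uncensored).
#' @param covariates character vector of baseline covariate column names.
#' @param validate logical; run [validate_episodes()] on the result (default
#'   `TRUE`).
#' @return An object of class `episode_table`: a list with elements
#'   \describe{
#'     \item{data}{sorted long-format data frame including the derived total
#'       gap `zij = xij + yij`,}
#'     \item{n}{number of subjects retained,}
#'     \item{subjects}{subject identifiers (as character),}
#'     \item{m, m_star}{episodes and effective episodes per subject,}
#'     \item{ci}{total observed follow-up per subject (the reconstruction of
#'       the censoring time \eqn{C_i}),}
#'     \item{covariate_names}{covariates carried along,}
#'     \item{n_dropped_missing}{subjects removed for missing values.}
#'   }
#' @examples
#' tab <- episode_table(data.frame(
#'   id = c(1, 1, 2), epi = c(1, 2, 1),
#'   xij = c(2, 4, 5), yij = c(3, 2, 0),
#'   d1 = c(1, 1, 0), d2 = c(1, 0, 0)),
#'   id = "id", episode = "epi")
#' tab$m_star
#' @seealso [validate_episodes()], [read_episodes()], [sim_bivgap()]
#' @export
episode_table <- function(data, id = "id", episode = "epi", xij = "xij",
                          yij = "yij", d1 = "d1", d2 = "d2",
                          covariates = character(), validate = TRUE) {
  if (!is.data.frame(data)) stop("`data` must be a data frame", call. = FALSE)
  if (nrow(data) == 0L) stop("input table is empty", call. = FALSE)
  required <- c(id = id, episode = episode, xij = xij, yij = yij,
                d1 = d1, d2 = d2)
  for (col in c(required, covariates)) {
    if (!col %in% names(data))
      stop(sprintf("column '%s' not found in input data", col), call. = FALSE)
  }
  df <- data.frame(
    id = as.character(data[[id]]),
    episode = data[[episode]],
    xij = as.numeric(data[[xij]]),
    yij = as.numeric(data[[yij]]),
    d1 = data[[d1]],
    d2 = data[[d2]],
    stringsAsFactors = FALSE
  )
  for (cv in covariates) df[[cv]] <- data[[cv]]

  # whole-subject deletion on any missing value
  n_total <- length(unique(df$id))
  ok_row <- complete.cases(df)
  bad_ids <- unique(df$id[!ok_row])
  df <- df[!(df$id %in% bad_ids), , drop = FALSE]
  n_dropped <- length(bad_ids)
  if (nrow(df) == 0L)
    stop("no subjects left after removing missing values", call. = FALSE)
  if (n_dropped > 0L)
    message(sprintf("%d of %d subjects used (%d dropped for missing values)",
                    n_total - n_dropped, n_total, n_dropped))

  ord <- order(df$id, df$episode)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df$zij <- df$xij + df$yij

  ids <- unique(df$id)
  idx <- match(df$id, ids)
  m <- as.integer(tabulate(idx, nbins = length(ids)))
  m_star <- ifelse(m >= 2L, m - 1L, 1L)
  ci <- as.numeric(tapply(df$zij, idx, sum))

  tab <- structure(list(
    data = df,
    n = length(ids),
    subjects = ids,
    m = setNames(m, ids),
    m_star = setNames(m_star, ids),
    ci = setNames(ci, ids),
    covariate_names = covariates,
    n_dropped_missing = n_dropped
  ), class = "episode_table")
  if (validate) validate_episodes(tab) else tab
}

#' Validate an episode table
#'
#' Checks the structural rules of bivariate alternating recurrent event data:
#' non-negative gap lengths, consecutive integer episode numbers within each
#' subject, censoring indicators in \{0, 1\} with the admissible patterns
#' (never `(d1, d2) = (0, 1)`; the last episode always has `d2 = 0`; earlier
#' episodes are fully observed), at least one subject with an uncensored
#' episode, and no zero-length gap flagged as uncensored (log-linear
#' regression of gap times is undefined at zero). Any violation raises an
#' error whose message begins with `"Error: Data not cleaned"` followed by a
#' detail line naming the offending subject and rule.
#'
#' When a subject's last episode has `(d1, d2) = (1, 1)` -- typically caused
#' by a censoring event recorded on the same day as the last observed event --
#' the error suggests adding a small quantity to the censoring time.
#'
#' @param table an [episode_table()] object.
#' @return the table, unchanged, invisibly on success.
#' @export
validate_episodes <- function(table) {
  stopifnot(inherits(table, "episode_table"))
  df <- table$data
  fail <- function(detail) {
    stop(sprintf("Error: Data not cleaned\n  %s", detail), call. = FALSE)
  }
  if (any(df$xij < 0) || any(df$yij < 0)) {
    bad <- df$id[df$xij < 0 | df$yij < 0][1L]
    fail(sprintf("subject %s has a negative gap time", bad))
  }
  if (!all(df$d1 %in% c(0, 1)) || !all(df$d2 %in% c(0, 1))) {
    bad <- df$id[!(df$d1 %in% c(0, 1)) | !(df$d2 %in% c(0, 1))][1L]
    fail(sprintf("subject %s has censoring indicators outside {0,1}", bad))
  }
  by_subj <- split(seq_len(nrow(df)), match(df$id, table$subjects))
  for (k in seq_along(by_subj)) {
    rows <- by_subj[[k]]
    sid <- table$subjects[k]
    ep <- df$episode[rows]
    if (any(ep != as.integer(ep)) || !identical(as.integer(ep),
                                                seq_along(rows))) {
      fail(sprintf(
        "subject %s has gaps or non-integers in the episode variable", sid))
    }
    last <- rows[length(rows)]
    early <- rows[-length(rows)]
    if (any(df$d1[rows] == 0 & df$d2[rows] == 1))
      fail(sprintf("subject %s has (d1, d2) = (0, 1) in an episode", sid))
    if (df$d1[last] == 1 && df$d2[last] == 1)
      fail(sprintf(paste(
        "subject %s has (d1, d2) = (1, 1) for the last episode;",
        "if the censoring event occurred on the same day as the last",
        "observed event, add a small quantity to the censoring time"), sid))
    if (df$d2[last] == 1)
      fail(sprintf("subject %s has d2 = 1 in the last episode", sid))
    if (length(early) && any(df$d1[early] != 1 | df$d2[early] != 1))
      fail(sprintf(
        "subject %s has a censored episode before the last one", sid))
    zero_unc <- (df$xij[rows] == 0 & df$d1[rows] == 1) |
      (df$yij[rows] == 0 & df$d2[rows] == 1)
    if (any(zero_unc))
      fail(sprintf("subject %s has an uncensored gap of length zero", sid))
  }
  if (all(df$d2 == 0))
    fail("no subject has any uncensored episode (all d2 = 0)")
  invisible(table)
}

#' Check that covariates are time-invariant
#'
#' The accelerated failure time model in this package admits baseline
#' covariates only. Any covariate that varies across a subject's episodes
#' raises the error `"Error: Time-varying covariates not allowed"`.
#'
#' @param table an [episode_table()] object.
#' @param covariates covariate names to check; defaults to all covariates
#'   carried by the table. A table without covariates passes vacuously.
#' @return the table, invisibly, on success.
#' @export
check_time_invariant_covariates <- function(table,
                                            covariates = table$covariate_names) {
  stopifnot(inherits(table, "episode_table"))
  df <- table$data
  for (cv in covariates) {
    n_lev <- tapply(df[[cv]], df$id, function(v) length(unique(v)))
    if (any(n_lev > 1L))
      stop("Error: Time-varying covariates not allowed", call. = FALSE)
  }
  invisible(table)
}

#' Read / write long-format episode data
#'
#' `read_episodes()` reads a delimited file (comma- or tab-separated, guessed
#' from the extension unless `sep` is given) with a header row and builds an
#' [episode_table()]; empty fields and `NA` are treated as missing.
#' `write_episodes()` writes the long-format rows back to CSV, so that a
#' read/write round trip reproduces the data up to column order.
#'
#' @param file path to a delimited text file.
#' @param sep field separator; default guesses `"\t"` for `.tsv`, `","`
#'   otherwise.
#' @param ... passed on to [episode_table()] (column mapping, covariates).
#' @return `read_episodes()` an `episode_table`; `write_episodes()` the file
#'   path, invisibly.
#' @export
read_episodes <- function(file, sep = NULL, ...) {
  if (!file.exists(file)) stop(sprintf("cannot read '%s'", file), call. = FALSE)
  if (is.null(sep)) sep <- if (grepl("\\.tsv$", file, ignore.case = TRUE)) "\t" else ","
  raw <- read.csv(file, sep = sep, na.strings = c("", "NA"),
                  stringsAsFactors = FALSE)
  episode_table(raw, ...)
}

#' @rdname read_episodes
#' @param table an `episode_table` to write.
#' @export
write_episodes <- function(table, file) {
  stopifnot(inherits(table, "episode_table"))
  out <- table$data
  out$zij <- NULL
  names(out)[names(out) == "episode"] <- "epi"
  write.csv(out, file, row.names = FALSE)
  invisible(file)
}

#' @export
print.episode_table <- function(x, ...) {
  cat(sprintf(
    "Bivariate alternating recurrent event data: %d subjects, %d episodes\n",
    x$n, nrow(x$data)))
  cat(sprintf("  episodes per subject: %d-%d (median %g)\n",
              min(x$m), max(x$m), stats::median(x$m)))
  if (length(x$covariate_names))
    cat("  covariates:", paste(x$covariate_names, collapse = ", "), "\n")
  if (x$n_dropped_missing > 0)
    cat(sprintf("  %d subjects dropped for missing values\n",
                x$n_dropped_missing))
  cat("\n")
  print(head(x$data, 6L))
  invisible(x)
}

#' @export
summary.episode_table <- function(object, ...) {
  with(object, data.frame(
    n = n,
    episodes = nrow(data),
    median_m = stats::median(m),
    censored_first_pair = sum(m == 1L),
    dropped_missing = n_dropped_missing
  ))
}
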