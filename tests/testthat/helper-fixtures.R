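# Toy table used throughout: three subjects with 2, 3 and 1 episodes.
t1_df <- function() {
  data.frame(
    id  = c(1, 1, 2, 2, 2, 3),
    epi = c(1, 2, 1, 2, 3, 1),
    xij = c(2, 4, 1, 3, 2, 5),
    yij = c(3, 2, 1, 4, 1, 0),
    d1  = c(1, 1, 1, 1, 0, 0),
    d2  = c(1, 0, 1, 1, 0, 0))
}

t1_table <- function(covariate = NULL) {
  df <- t1_df()
  if (!is.null(covariate)) {
    df$a1 <- rep(covariate, times = c(2, 3, 1))
    return(episode_table(df, covariates = "a1"))
  }
  episode_table(df)
}

# Random small valid tables (n subjects, up to 3 episodes each); subject 1 is
# forced to have an uncensored episode so the table always validates.
random_table <- function(seed, n = 5, with_covariate = FALSE) {
  set.seed(seed)
  rows <- lapply(seq_len(n), function(i) {
    m <- if (i == 1) sample(2:3, 1) else sample(1:3, 1)
    x <- round(runif(m, 0.5, 5), 2)
    y <- round(runif(m, 0.5, 5), 2)
    d1 <- rep(1, m); d2 <- rep(1, m)
    d2[m] <- 0
    if (runif(1) < 0.4) {            # censor the last Type I gap too
      d1[m] <- 0
      y[m] <- 0
    } else {
      y[m] <- round(y[m] / 2, 2)     # partially observed break
    }
    data.frame(id = i, epi = seq_len(m), xij = x, yij = y, d1 = d1, d2 = d2)
  })
  df <- do.call(rbind, rows)
  if (with_covariate) {
    a <- stats::rbinom(n, 1, 0.5)
    a[1] <- 1; a[min(2, n)] <- 0     # guarantee variation
    df$a1 <- a[df$id]
    return(episode_table(df, covariates = "a1"))
  }
  episode_table(df)
}

# ---- independent brute-force oracles (naive loops, straight from the
# displayed estimators; deliberately unoptimized) -------------------------

# per-subject episode list restricted to j <= m*
oracle_episodes <- function(tab) {
  df <- tab$data
  lapply(tab$subjects, function(s) {
    rows <- df[df$id == s, , drop = FALSE]
    m <- nrow(rows)
    ms <- if (m >= 2) m - 1 else 1
    list(m = m, ms = ms, x = rows$xij[seq_len(ms)], y = rows$yij[seq_len(ms)],
         z = rows$zij[seq_len(ms)], d2 = rows$d2[seq_len(ms)],
         d1 = rows$d1[seq_len(ms)], ci = sum(rows$zij))
  })
}

oracle_H <- function(eps, n, z, x, y, ai) {
  tot <- 0
  for (e in eps) {
    a <- if (ai == 2) e$ci else 1
    if (e$m < 2) next
    for (j in seq_len(e$ms))
      if (e$z[j] == z && e$x[j] <= x && e$y[j] <= y)
        tot <- tot + a / e$ms
  }
  tot / n
}

oracle_R <- function(eps, n, z, ai) {
  tot <- 0
  for (e in eps) {
    a <- if (ai == 2) e$ci else 1
    for (j in seq_len(e$ms)) if (e$z[j] >= z) tot <- tot + a / e$ms
  }
  tot / n
}

brute_joint_cdf <- function(tab, x, y, ai = 1) {
  eps <- oracle_episodes(tab)
  n <- tab$n
  tk <- sort(unique(unlist(lapply(eps, function(e) e$z[e$d2 == 1]))))
  total <- 0
  for (k in seq_along(tk)) {
    if (tk[k] > x + y) break
    pref <- 1
    for (l in seq_len(k - 1))
      pref <- pref * (1 - oracle_H(eps, n, tk[l], Inf, Inf, ai) /
                        oracle_R(eps, n, tk[l], ai))
    total <- total + pref * oracle_H(eps, n, tk[k], x, y, ai) /
      oracle_R(eps, n, tk[k], ai)
  }
  total
}

brute_marginal_surv <- function(tab, x, ai = 1) {
  eps <- oracle_episodes(tab)
  n <- tab$n
  xk <- sort(unique(unlist(lapply(eps, function(e)
    if (e$m >= 2) e$x[e$d1 == 1] else numeric(0)))))
  s <- 1
  for (t in xk[xk <= x]) {
    H <- 0; R <- 0
    for (e in eps) {
      a <- if (ai == 2) e$ci else 1
      for (j in seq_len(e$ms)) {
        if (e$m >= 2 && e$x[j] == t) H <- H + a / e$ms
        if (e$x[j] >= t) R <- R + a / e$ms
      }
    }
    s <- s * (1 - H / R)
  }
  s
}

# naive evaluation of the rank-based estimating functions: sequential
# transforms, explicit double loops for the risk-set sums
brute_chang_U <- function(tab, b, covariates = tab$covariate_names) {
  df <- tab$data
  p <- length(covariates)
  b1 <- b[seq_len(p)]; b2 <- b[p + seq_len(p)]
  subj <- list()
  for (s in tab$subjects) {
    rows <- df[df$id == s, , drop = FALSE]
    A <- as.numeric(rows[1, covariates])
    ci <- sum(rows$zij)
    m <- nrow(rows); ms <- if (m >= 2) m - 1 else 1
    xt <- zt <- dx <- dz <- numeric(m)
    cum <- 0
    for (j in seq_len(m)) {
      x0 <- rows$xij[j] * exp(-sum(A * b1))
      z0 <- rows$xij[j] * exp(-sum(A * b1)) + rows$yij[j] * exp(-sum(A * b2))
      bound <- ci * exp(-sum(A * b1)) - cum
      xt[j] <- min(x0, bound); zt[j] <- min(z0, bound)
      dx[j] <- as.numeric(x0 < bound); dz[j] <- as.numeric(z0 < bound)
      cum <- cum + zt[j]
    }
    subj[[length(subj) + 1]] <- list(A = A, ms = ms, xt = xt[seq_len(ms)],
                                     zt = zt[seq_len(ms)],
                                     dx = dx[seq_len(ms)],
                                     dz = dz[seq_len(ms)])
  }
  n <- length(subj)
  Ufun <- function(get_t, get_d) {
    U <- numeric(p)
    for (si in subj) {
      for (j in seq_len(si$ms)) {
        if (get_d(si)[j] == 0) next
        t0 <- get_t(si)[j]
        S0 <- 0; S1 <- numeric(p)
        for (sk in subj) {
          for (l in seq_len(sk$ms)) {
            if (get_t(sk)[l] >= t0) {
              S0 <- S0 + 1 / sk$ms / n
              S1 <- S1 + sk$A / sk$ms / n
            }
          }
        }
        U <- U + (si$A - S1 / S0) / si$ms
      }
    }
    U / sqrt(n)
  }
  list(U1 = Ufun(function(s) s$xt, function(s) s$dx),
       U2 = Ufun(function(s) s$zt, function(s) s$dz))
}

# naive quadruple-loop evaluation of the U-statistic estimating functions
brute_lee_D <- function(tab, b, km1, km2, covariates = tab$covariate_names) {
  df <- tab$data
  p <- length(covariates)
  b1 <- b[seq_len(p)]; b2 <- b[p + seq_len(p)]
  n <- tab$n
  A <- lapply(tab$subjects, function(s)
    as.numeric(df[df$id == s, covariates, drop = FALSE][1, ]))
  eps <- lapply(tab$subjects, function(s) {
    rows <- df[df$id == s, , drop = FALSE]
    m <- nrow(rows); ms <- if (m >= 2) m - 1 else 1
    list(ms = ms, x = rows$xij[seq_len(ms)], y = rows$yij[seq_len(ms)],
         z = rows$zij[seq_len(ms)], d1 = rows$d1[seq_len(ms)],
         d2 = rows$d2[seq_len(ms)])
  })
  D1 <- numeric(p); D2 <- numeric(p)
  for (i in seq_len(n)) {
    for (ip in seq_len(n)) {
      Aii <- A[[ip]] - A[[i]]
      e <- eps[[i]]
      for (j in seq_len(e$ms)) {
        if (e$d1[j] == 1) {
          tx <- exp(sum(Aii * b1)) * e$x[j]
          O1 <- log(min(max(tx, e$x[j]), km1$L)) - log(km1$L)
          D1 <- D1 + Aii * e$d1[j] * O1 / (e$ms * km1$Gmin(e$x[j]))
        }
        if (e$d2[j] == 1) {
          tz <- exp(sum(Aii * b1)) * e$x[j] + exp(sum(Aii * b2)) * e$y[j]
          O2 <- log(min(max(tz, e$z[j]), km2$L)) - log(km2$L)
          D2 <- D2 + Aii * e$d2[j] * O2 / (e$ms * km2$Gmin(e$z[j]))
        }
      }
    }
  }
  list(D1 = D1 / n^2, D2 = D2 / n^2)
}
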