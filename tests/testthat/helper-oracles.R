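# Independent reference implementations, written as direct transcriptions of
# the defining formulas (plain double loops, no engine code), used to
# cross-check the sequential engines.

# level recursion of the plain graph: alpha_i = (tau-lam)(alpha*gamma_i +
# sum_j w(j,i) U_j alpha_j/(tau-lam)), with an explicit weight function
oracle_graph <- function(p, gamvals, wfun, alpha, tau, lam) {
  n <- length(p)
  tau <- rep_len(tau, n); lam <- rep_len(lam, n)
  at <- numeric(n); u <- integer(n)
  for (i in seq_len(n)) {
    v <- alpha * gamvals[i]
    if (i > 1) for (j in seq_len(i - 1))
      v <- v + wfun(j, i, u[seq_len(j - 1)]) * u[j] * at[j]
    at[i] <- v
    u[i] <- as.integer(p[i] <= lam[i] || p[i] > tau[i])
  }
  (tau - lam) * at
}

# local spending levels, straight from the position formula
oracle_spending <- function(p, gamvals, lags, alpha, tau, lam) {
  n <- length(p)
  tau <- rep_len(tau, n); lam <- rep_len(lam, n)
  lags <- rep_len(lags, n)
  u <- integer(n); lev <- numeric(n)
  for (i in seq_len(n)) {
    pre <- seq_len(max(0, i - lags[i] - 1))
    t_loc <- 1 + lags[i] + sum(1 - u[pre])
    lev[i] <- alpha * (tau[i] - lam[i]) * gamvals[t_loc]
    u[i] <- as.integer(p[i] <= lam[i] || p[i] > tau[i])
  }
  lev
}

# closed spending levels: rejections inside the lag window do not advance
# the schedule position
oracle_closed_spending <- function(p, gamvals, lags, alpha, tau, lam) {
  n <- length(p)
  tau <- rep_len(tau, n); lam <- rep_len(lam, n)
  lags <- rep_len(lags, n)
  u <- integer(n); r <- integer(n); lev <- numeric(n)
  for (i in seq_len(n)) {
    pre <- seq_len(max(0, i - lags[i] - 1))
    win <- if (lags[i] > 0) (i - lags[i]):(i - 1) else integer(0)
    t_c <- 1 + sum(1 - r[win]) + sum(1 - pmax(u[pre], r[pre]))
    lev[i] <- alpha * (tau[i] - lam[i]) * gamvals[t_c]
    u[i] <- as.integer(p[i] <= lam[i] || p[i] > tau[i])
    r[i] <- as.integer(p[i] <= lev[i])
  }
  lev
}

# condition-1 spend of a finished run
budget_spend <- function(result, tau, lam) {
  n <- nrow(result)
  tau <- rep_len(tau, n); lam <- rep_len(lam, n)
  sum(result$scaled_level[result$p > lam & result$p <= tau])
}

# a random p-value stream: mixture of small (candidate), large (discardable)
# and mid-range (spending) values
rand_stream <- function(n) {
  grp <- sample(1:3, n, replace = TRUE)
  ifelse(grp == 1, runif(n, 0, 0.1),
         ifelse(grp == 2, runif(n, 0.9, 1), runif(n)))
}

# a random valid lag sequence: L_1 = 0, L_{i+1} <= L_i + 1
rand_lags <- function(n, p_grow = 0.4) {
  lags <- integer(n)
  for (i in seq_len(n)[-1])
    lags[i] <- sample(0:min(i - 1, lags[i - 1] + 1), 1,
                      prob = c(rep(1 - p_grow, 1),
                               rep(p_grow / max(1, min(i - 1, lags[i - 1] + 1)),
                                   min(i - 1, lags[i - 1] + 1))))
  lags
}

gamma_families_for_tests <- function() {
  list(geometric = make_gamma("geometric", q = 0.6),
       quadratic = make_gamma("quadratic"),
       log_series = make_gamma("log_series", horizon = 2000),
       power_series = make_gamma("power_series", exponent = 1.6,
                                 horizon = 2000))
}
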