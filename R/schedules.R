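# Initial-weight schedules (gamma) and transfer-weight families (g).
#
# A gamma schedule assigns every hypothesis i = 1, 2, ... a nonnegative
# initial weight gamma_i with sum_{i} gamma_i <= 1: gamma_i is the fraction
# of the overall level alpha that hypothesis i receives unconditionally.
# Transfer weights g_{j,i} (i > j) route the unspent level of hypothesis j
# to future hypotheses; each row must satisfy sum_{i>j} g_{j,i} <= 1.

.WSUM_TOL <- 1e-12

#' Construct an initial-weight schedule
#'
#' Builds a schedule of nonnegative initial weights \eqn{\gamma_i} with
#' \eqn{\sum_i \gamma_i \le 1}, used by all graph and spending procedures to
#' seed the per-hypothesis significance levels \eqn{\alpha \gamma_i}.
#'
#' Available families:
#' \describe{
#'   \item{`geometric`}{\eqn{\gamma_i = q^{i-1}(1-q)} for \eqn{q \in (0,1)};
#'     sums to exactly 1, partial sums are \eqn{1 - q^i}. The larger `q`,
#'     the more slowly the schedule decays and the more hypotheses it can
#'     cover before the level is effectively exhausted.}
#'   \item{`quadratic`}{\eqn{\gamma_i = 6/(\pi^2 i^2)}; sums to exactly 1
#'     (Basel series).}
#'   \item{`log_series`}{\eqn{\gamma_i \propto 1/((i+1)\log(i+1)^2)},
#'     normalized over a finite `horizon` so the truncated sum equals 1;
#'     the tail past the horizon is treated as unspent.}
#'   \item{`power_series`}{\eqn{\gamma_i \propto i^{-s}} with exponent
#'     \eqn{s > 1}, normalized over `horizon` like `log_series`.}
#'   \item{`custom`}{a user-supplied finite nonincreasing-or-not vector of
#'     nonnegative weights with sum at most 1; indices past its length get
#'     weight 0.}
#' }
#'
#' All built-in families are nonincreasing in `i`, which is required by the
#' spending-equivalent and conflict-adjusted transfer constructions.
#'
#' @param family One of `"geometric"`, `"quadratic"`, `"log_series"`,
#'   `"power_series"`, `"custom"`.
#' @param q Decay parameter of the geometric family, in (0, 1).
#' @param exponent Exponent of the power-series family, must exceed 1.
#' @param horizon Normalization horizon for families without a closed-form
#'   infinite sum (default 10000).
#' @param weights Numeric vector of weights for the custom family.
#' @return An object of class `gamma_schedule`.
#' @examples
#' g <- make_gamma("geometric", q = 0.5)
#' gamma_values(g, 4)            # 1/2, 1/4, 1/8, 1/16
#' gamma_tail(g, 3)              # q^3 = 1/8
#' @export
make_gamma <- function(family = c("geometric", "quadratic", "log_series",
                                  "power_series", "custom"),
                       q = 0.5, exponent = 1.6, horizon = 10000L,
                       weights = NULL) {
  family <- match.arg(family)
  params <- list()
  switch(family,
    geometric = {
      if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
        stop("geometric schedule requires 0 < q < 1", call. = FALSE)
      params$q <- q
      fun <- function(i) ifelse(i >= 1, q^(i - 1) * (1 - q), 0)
      tail_fun <- function(n) q^n
    },
    quadratic = {
      fun <- function(i) ifelse(i >= 1, 6 / (pi^2 * i^2), 0)
      tail_fun <- function(n) 6 / pi^2 * trigamma(n + 1)
    },
    log_series = {
      horizon <- .check_horizon(horizon)
      params$horizon <- horizon
      idx <- seq_len(horizon)
      raw <- 1 / ((idx + 1) * log(idx + 1)^2)
      w <- raw / sum(raw)
      fun <- function(i) ifelse(i >= 1 & i <= horizon, w[pmax(pmin(i, horizon), 1)], 0)
      tail_fun <- function(n) max(0, 1 - sum(w[seq_len(min(n, horizon))]))
    },
    power_series = {
      if (!is.numeric(exponent) || length(exponent) != 1L || exponent <= 1)
        stop("power-series schedule requires exponent > 1", call. = FALSE)
      horizon <- .check_horizon(horizon)
      params$exponent <- exponent
      params$horizon <- horizon
      idx <- seq_len(horizon)
      w <- idx^(-exponent)
      w <- w / sum(w)
      fun <- function(i) ifelse(i >= 1 & i <= horizon, w[pmax(pmin(i, horizon), 1)], 0)
      tail_fun <- function(n) max(0, 1 - sum(w[seq_len(min(n, horizon))]))
    },
    custom = {
      if (is.null(weights) || !is.numeric(weights) || any(weights < 0))
        stop("custom schedule requires a nonnegative numeric 'weights' vector",
             call. = FALSE)
      if (sum(weights) > 1 + .WSUM_TOL)
        stop("custom schedule weights must sum to at most 1", call. = FALSE)
      w <- as.numeric(weights)
      params$length <- length(w)
      fun <- function(i) ifelse(i >= 1 & i <= length(w), w[pmax(pmin(i, length(w)), 1)], 0)
      tail_fun <- function(n) max(0, sum(w) - sum(w[seq_len(min(n, length(w)))]))
      nonincreasing <- !is.unsorted(rev(w))
    }
  )
  nonincreasing <- if (family == "custom") nonincreasing else TRUE
  structure(
    list(fun = fun, tail_fun = tail_fun, family = family, params = params,
         nonincreasing = nonincreasing),
    class = "gamma_schedule"
  )
}

.check_horizon <- function(horizon) {
  if (!is.numeric(horizon) || length(horizon) != 1L || horizon < 1 ||
      !is.finite(horizon))
    stop("this schedule family requires a finite positive horizon for ",
         "normalization", call. = FALSE)
  as.integer(horizon)
}

#' Evaluate an initial-weight schedule
#'
#' @param gamma A `gamma_schedule` from [make_gamma()].
#' @param n Number of leading weights to return.
#' @return Numeric vector `gamma_1, ..., gamma_n`.
#' @export
gamma_values <- function(gamma, n) {
  stopifnot(inherits(gamma, "gamma_schedule"), n >= 0)
  if (n == 0) return(numeric(0))
  gamma$fun(seq_len(n))
}

#' Tail mass of an initial-weight schedule
#'
#' Returns \eqn{\sum_{i > n} \gamma_i}, in closed form for the geometric
#' (\eqn{q^n}) and quadratic (trigamma) families and by complement of the
#' normalized partial sum for horizon-truncated families.
#'
#' @inheritParams gamma_values
#' @param n Number of already-consumed indices.
#' @return The remaining schedule mass, a scalar in \[0, 1\].
#' @export
gamma_tail <- function(gamma, n) {
  stopifnot(inherits(gamma, "gamma_schedule"), n >= 0)
  gamma$tail_fun(n)
}

#' @export
print.gamma_schedule <- function(x, ...) {
  cat("<gamma_schedule> family:", x$family)
  if (length(x$params))
    cat(" (", paste(names(x$params), unlist(x$params), sep = "=",
                    collapse = ", "), ")", sep = "")
  cat("\n  first weights:",
      paste(signif(gamma_values(x, 5), 4), collapse = ", "), "...\n")
  invisible(x)
}

# Checks schedule invariants on the first n weights: nonnegativity, partial
# sums bounded by 1, and (if declared) monotone decrease.
validate_gamma <- function(gamma, n = 1000L) {
  g <- gamma_values(gamma, n)
  if (any(g < 0)) stop("gamma schedule has negative weights", call. = FALSE)
  if (any(cumsum(g) > 1 + .WSUM_TOL))
    stop("gamma schedule partial sums exceed 1", call. = FALSE)
  if (gamma$nonincreasing && any(diff(g) > .WSUM_TOL))
    stop("gamma schedule declared nonincreasing but increases", call. = FALSE)
  invisible(TRUE)
}

# t(j) = 1 + sum_{k < j} (1 - U_k): the position in the gamma schedule that
# hypothesis j occupies once reused (U_k = 1) indices are skipped.
t_index <- function(u_history) {
  n <- length(u_history)
  if (n == 0) return(integer(0))
  1L + c(0L, cumsum(1L - u_history[-n]))
}

# Spending-equivalent weight kernel: g_{j,i} expressed through the schedule
# positions, g = (gamma[t_j + d - 1] - gamma[t_j + d]) / gamma[t_j] where d
# is the transfer distance (d = i - j for plain streams, the nonconflicting
# rank for conflict-adjusted streams). Requires gamma nonincreasing.
lemma_weight <- function(gamvals, tj, d) {
  denom <- gamvals[tj]
  if (any(denom <= 0))
    stop("degenerate schedule: gamma[t(j)] = 0 where a transfer weight is ",
         "required", call. = FALSE)
  (gamvals[tj + d - 1L] - gamvals[tj + d]) / denom
}

#' Spending-equivalent transfer weights
#'
#' Constructs the transfer-weight family under which the ADDIS-Graph
#' reproduces ADDIS-Spending exactly:
#' \deqn{g_{j,i} = \frac{\gamma_{t(j)+i-j-1} - \gamma_{t(j)+i-j}}{\gamma_{t(j)}},
#'   \quad t(j) = 1 + \sum_{k<j}(1-U_k),}
#' where \eqn{U_k} indicates that hypothesis k's level was reused (its
#' p-value fell at or below \eqn{\lambda_k} or above \eqn{\tau_k}). Row sums
#' telescope: over `i = j+1, ..., j+M` they equal
#' \eqn{(\gamma_{t(j)} - \gamma_{t(j)+M})/\gamma_{t(j)} \le 1}.
#'
#' @param gamma A nonincreasing `gamma_schedule`.
#' @param u_history Integer/logical vector of reuse indicators
#'   \eqn{U_1, \ldots, U_m}; weights `w(j, i)` are available for `j <= m + 1`.
#' @return A `transfer_weights` object with a vectorized weight function
#'   `$w(j, i)` and row-tail function `$row_tail(j, n)` returning
#'   \eqn{\sum_{i > n} g_{j,i}}.
#' @examples
#' g <- make_gamma("geometric", q = 0.5)
#' tw <- spending_equivalent_weights(g, u_history = c(1, 0))
#' tw$w(1, 2:4)   # 1/2, 1/4, 1/8
#' @export
spending_equivalent_weights <- function(gamma, u_history = integer(0)) {
  stopifnot(inherits(gamma, "gamma_schedule"))
  if (!gamma$nonincreasing)
    stop("spending-equivalent weights require a nonincreasing gamma schedule",
         call. = FALSE)
  u <- as.integer(u_history)
  tj_all <- t_index(c(u, 0L))  # position defined for j up to length(u) + 1
  w <- function(j, i) {
    stopifnot(all(i > j))
    if (any(j > length(tj_all)))
      stop("u_history too short for requested source index j", call. = FALSE)
    m <- max(tj_all[j] + i - j)
    gv <- gamma_values(gamma, m)
    lemma_weight(gv, tj_all[j], i - j)
  }
  row_tail <- function(j, n) {
    stopifnot(length(j) == 1L, n >= j)
    gv <- gamma_values(gamma, tj_all[j] + n - j)
    gv[tj_all[j] + n - j] / gv[tj_all[j]]
  }
  structure(
    list(kind = "spending_equivalent", conflict_adjusted = FALSE,
         w = w, row_tail = row_tail, gamma = gamma, u_history = u),
    class = "transfer_weights"
  )
}

#' Conflict-adjusted uniform-improvement transfer weights
#'
#' Adjusts the spending-equivalent weights to a lag-type conflict structure
#' by index shifting: \eqn{g^*_{j,i} = 0} whenever \eqn{j \in X_i}, and for
#' nonconflicting pairs \eqn{g^*_{j,i}} equals the spending-equivalent
#' weight at distance `r(j, i)`, the rank of `i` among the future indices
#' not conflicting with `j`. Level that the plain spending construction
#' would park on conflicting (unusable) positions is thereby compressed onto
#' the nonconflicting ones, which makes the resulting graph levels dominate
#' the local ADDIS-Spending levels at every index.
#'
#' @inheritParams spending_equivalent_weights
#' @param conflicts A lag-representable `conflict_structure` (local
#'   dependence, \eqn{X_i = \{i-1, \ldots, i-L_i\}}).
#' @return A conflict-adjusted `transfer_weights` object.
#' @examples
#' g <- make_gamma("geometric", q = 0.5)
#' cs <- conflicts_from_lags(c(0, 1, 0))
#' tw <- conf_u_weights(g, cs, u_history = c(1, 0))
#' tw$w(1, 2:3)   # 0 (conflict), then 1/2
#' @export
conf_u_weights <- function(gamma, conflicts, u_history = integer(0)) {
  stopifnot(inherits(gamma, "gamma_schedule"),
            inherits(conflicts, "conflict_structure"))
  if (!gamma$nonincreasing)
    stop("conflict-adjusted weights require a nonincreasing gamma schedule",
         call. = FALSE)
  if (is.null(conflicts$lags))
    stop("conflict-adjusted uniform-improvement weights are defined for ",
         "lag-representable (local dependence) conflict structures only",
         call. = FALSE)
  u <- as.integer(u_history)
  tj_all <- t_index(c(u, 0L))
  lags <- conflicts$lags
  # rank of i among {k > j : j not in X_k}; beyond the recorded structure
  # future indices are taken as nonconflicting
  rank_of <- function(j, i) {
    ks <- (j + 1L):i
    Lk <- ifelse(ks <= length(lags), lags[pmin(ks, length(lags))], 0L)
    ok <- ks - Lk > j
    cumsum(ok)[i - j] * ok[i - j]  # 0 when i itself conflicts with j
  }
  w <- function(j, i) {
    stopifnot(length(j) == 1L, all(i > j))
    if (j > length(tj_all))
      stop("u_history too short for requested source index j", call. = FALSE)
    r <- vapply(i, function(ii) rank_of(j, ii), numeric(1))
    out <- numeric(length(i))
    pos <- r > 0
    if (any(pos)) {
      gv <- gamma_values(gamma, tj_all[j] + max(r))
      out[pos] <- lemma_weight(gv, tj_all[j], r[pos])
    }
    out
  }
  row_tail <- function(j, n) {
    stopifnot(length(j) == 1L, n >= j)
    r_n <- if (n > j) rank_count(j, n, lags) else 0L
    gv <- gamma_values(gamma, tj_all[j] + r_n + 1L)
    gv[tj_all[j] + r_n] / gv[tj_all[j]]
  }
  structure(
    list(kind = "conf_u", conflict_adjusted = TRUE, w = w,
         row_tail = row_tail, gamma = gamma, u_history = u,
         conflicts = conflicts),
    class = "transfer_weights"
  )
}

# number of indices k in (j, n] that do not conflict with j
rank_count <- function(j, n, lags) {
  ks <- (j + 1L):n
  Lk <- ifelse(ks <= length(lags), lags[pmin(ks, length(lags))], 0L)
  sum(ks - Lk > j)
}

#' Geometric transfer weights
#'
#' Fixed transfer family \eqn{g_{j,i} = q^{i-j-1}(1-q)} (row sums exactly 1).
#' For `q = 1/2` this is \eqn{g_{j,i} = (1/2)^{i-j}}.
#'
#' @param q Decay parameter in (0, 1).
#' @return A `transfer_weights` object.
#' @export
geometric_transfer <- function(q = 0.5) {
  if (!is.numeric(q) || length(q) != 1L || q <= 0 || q >= 1)
    stop("geometric transfer requires 0 < q < 1", call. = FALSE)
  structure(
    list(kind = "geometric", conflict_adjusted = FALSE, q = q,
         w = function(j, i) q^(i - j - 1) * (1 - q),
         row_tail = function(j, n) q^(n - j)),
    class = "transfer_weights"
  )
}

#' Custom transfer-weight table
#'
#' Wraps an explicit table of transfer weights, e.g. read from a CSV with
#' columns `j`, `i`, `weight`. Row sums are validated against the budget
#' constraint \eqn{\sum_{i>j} g_{j,i} \le 1}.
#'
#' @param table Data frame with columns `j`, `i`, `weight` (`i > j`,
#'   `weight >= 0`).
#' @param conflict_adjusted Declare the table as conflict-adjusted; engines
#'   then verify that no positive weight sits on a conflicting pair.
#' @return A `transfer_weights` object.
#' @export
transfer_table <- function(table, conflict_adjusted = FALSE) {
  stopifnot(is.data.frame(table), all(c("j", "i", "weight") %in% names(table)))
  if (any(table$i <= table$j))
    stop("transfer table requires i > j in every row", call. = FALSE)
  if (any(table$weight < 0))
    stop("transfer weights must be nonnegative", call. = FALSE)
  rs <- tapply(table$weight, table$j, sum)
  if (any(rs > 1 + .WSUM_TOL))
    stop("transfer table row sums exceed 1 for source index j = ",
         names(rs)[which(rs > 1 + .WSUM_TOL)[1]], call. = FALSE)
  key <- paste(table$j, table$i)
  lookup <- stats::setNames(table$weight, key)
  w <- function(j, i) {
    v <- unname(lookup[paste(j, i)])
    ifelse(is.na(v), 0, v)
  }
  row_tail <- function(j, n) {
    sel <- table$j == j & table$i > n
    sum(table$weight[sel])
  }
  structure(
    list(kind = "custom_table", conflict_adjusted = conflict_adjusted,
         w = w, row_tail = row_tail, table = table),
    class = "transfer_weights"
  )
}

#' @export
print.transfer_weights <- function(x, ...) {
  cat("<transfer_weights> kind:", x$kind,
      if (isTRUE(x$conflict_adjusted)) "(conflict-adjusted)" else "", "\n")
  invisible(x)
}
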