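# FDR-controlling ADDIS-Graph.
#
# Wealth view: the stream starts with W0 <= alpha. Unspent level (U_j = 1)
# is recycled along g* exactly as in the FWER graph. In addition, every
# rejection releases fresh wealth distributed along h*: the first rejection
# releases (alpha - W0) -- topping the stream up to a full alpha -- and each
# later rejection releases a full alpha. This matches the generalized
# alpha-investing convention that no level is gained for the very first
# rejection beyond restoring the initial hold-back.

#' FDR ADDIS-Graph under conflict sets
#'
#' Tests each hypothesis at
#' \deqn{\alpha_i = (\tau_i - \lambda_i)\,\tilde\alpha_i, \qquad
#'  \tilde\alpha_i = W_0\gamma_i + \sum_{j<i} g^*_{j,i} U_j \tilde\alpha_j
#'   + \sum_{j<i} h^*_{j,i} R_j\big[(\alpha - W_0)K_j^c + \alpha K_j\big],}
#' where \eqn{R_j = 1\{P_j \le \alpha_j\}} and \eqn{K_j} indicates that the
#' first rejection happened within the first \eqn{j - 1} steps
#' (\eqn{K_j^c = 1 - K_j}). The procedure controls the modified FDR
#' (ratio of expectations) at level `alpha` under arbitrary monotone
#' conflict sets and the FDR under independence. On a stream with no
#' rejections it coincides exactly with [addis_graph_conf()] run at overall
#' level `w0`.
#'
#' @inheritParams addis_graph_conf
#' @param alpha Target (m)FDR level in (0, 1).
#' @param w0 Initial wealth, \eqn{0 < W_0 \le \alpha}. Default `alpha / 2`,
#'   the common half-split of online alpha-investing wealth algorithms.
#' @param tau,lam Thresholds; the recommended FDR defaults are
#'   \eqn{\tau = 0.5}, \eqn{\lambda = 0.25}.
#' @param g_star,h_star Transfer specifications for the reuse and
#'   rejection-gain weights; both default to the `"conf_u"` construction
#'   (the gain weights have the same constraints as the reuse weights).
#' @param conflicts Conflict structure; `NULL` for an independent stream.
#' @return An `addis_result` data frame with an extra column `k` (first
#'   rejection seen strictly before this index).
#' @export
fdr_addis_graph <- function(p, gamma, conflicts = NULL,
                            g_star = "conf_u", h_star = "conf_u",
                            alpha = 0.2, w0 = alpha / 2,
                            tau = 0.5, lam = 0.25) {
  p <- .check_p(p)
  n <- length(p)
  hp <- .check_hp(alpha, tau, lam, n)
  if (!is.numeric(w0) || length(w0) != 1L || w0 <= 0 || w0 > alpha)
    stop("initial wealth w0 must satisfy 0 < w0 <= alpha", call. = FALSE)
  if (is.null(conflicts)) conflicts <- conflicts_from_lags(integer(n))
  lags <- lags_of_or_general(conflicts, n)
  stopifnot(inherits(gamma, "gamma_schedule"))
  trg <- .resolve_transfer(g_star, gamma)
  trh <- .resolve_transfer(h_star, gamma)
  gam <- gamma_values(gamma, 2L * n + 2L)

  at <- numeric(n); u <- integer(n); r <- integer(n); k <- integer(n)
  tj <- integer(n); cntg <- integer(n); cnth <- integer(n)
  spent <- numeric(n); tot <- 0

  # returns the conflict-respecting weight vector for sources j < i, plus
  # the updated nonconflicting-successor counter (used by conf_u shifting)
  weight_vec <- function(tr, cnt, i, nonconf, j) {
    w <- numeric(i - 1L)
    idx <- j[nonconf]
    if (tr$kind == "conf_u") {
      cnt[idx] <- cnt[idx] + 1L
      if (length(idx)) w[nonconf] <- lemma_weight(gam, tj[idx], cnt[idx])
    } else if (tr$kind == "spending_equivalent") {
      if (length(idx)) w[nonconf] <- lemma_weight(gam, tj[idx], i - idx)
    } else if (tr$kind == "callback") {
      w <- rep_len(as.numeric(tr$fn(j, i, u[j])), i - 1L)
      if (any(w[!nonconf] > .WSUM_TOL))
        stop("transfer/conflict mismatch: positive weight on conflicting pair",
             call. = FALSE)
      w[!nonconf] <- 0
    } else {
      w <- tr$obj$w(j, i)
      if (any(w[!nonconf] > .WSUM_TOL))
        stop("transfer/conflict mismatch: positive weight on conflicting pair",
             call. = FALSE)
      w[!nonconf] <- 0
    }
    list(w = w, cnt = cnt)
  }

  for (i in seq_len(n)) {
    tj[i] <- if (i == 1L) 1L else tj[i - 1L] + (1L - u[i - 1L])
    k[i] <- as.integer(i > 1L && any(r[seq_len(i - 1L)] == 1L))
    v <- w0 * gam[i]
    if (i > 1L) {
      j <- seq_len(i - 1L)
      nonconf <- j < i - lags[i]
      resg <- weight_vec(trg, cntg, i, nonconf, j); cntg <- resg$cnt
      resh <- weight_vec(trh, cnth, i, nonconf, j); cnth <- resh$cnt
      gains <- ifelse(k[j] == 1L, alpha, alpha - w0)
      v <- v + sum(resg$w * u[j] * at[j]) + sum(resh$w * r[j] * gains)
    }
    at[i] <- v
    level <- (hp$tau[i] - hp$lam[i]) * v
    u[i] <- as.integer(p[i] <= hp$lam[i] || p[i] > hp$tau[i])
    r[i] <- as.integer(p[i] <= level)
    if (p[i] > hp$lam[i] && p[i] <= hp$tau[i]) tot <- tot + v
    spent[i] <- tot
  }
  df <- data.frame(index = seq_len(n), p = p,
                   level = (hp$tau - hp$lam) * at, scaled_level = at,
                   u = u, rejected = r == 1L, k = k, spent_so_far = spent)
  structure(df, class = c("addis_result", "data.frame"),
            procedure = "fdr-addis-graph",
            alpha = alpha, w0 = w0, gamma = gamma,
            transfer_kind = trg$kind, transfer = trg, lags = lags,
            tj = tj, cnt = cntg, at = at, u = u)
}

#' Estimate FDR and modified FDR from simulation replications
#'
#' The modified FDR is the ratio of expectations
#' \eqn{\mathrm{mFDR} = E|V| / E(|R| \vee 1)} (false rejections over
#' rejections, each averaged across replications before taking the ratio);
#' the FDR is the expectation of the per-replication ratio
#' \eqn{E[|V|/(|R| \vee 1)]}. Standard errors use the delta method for the
#' mFDR ratio and the empirical standard deviation for the FDR.
#'
#' @param results Data frame with one row per replication and columns `v`
#'   (number of false rejections) and `r` (number of rejections).
#' @return List with `mfdr`, `fdr`, `mfdr_se`, `fdr_se`, `reps`.
#' @examples
#' estimate_mfdr(data.frame(v = c(1, 0), r = c(2, 0)))  # mFDR = 1/3
#' @export
estimate_mfdr <- function(results) {
  stopifnot(is.data.frame(results), all(c("v", "r") %in% names(results)))
  m <- nrow(results)
  if (m == 0) stop("empty replication set", call. = FALSE)
  v <- results$v
  denom <- pmax(results$r, 1)
  mfdr <- mean(v) / mean(denom)
  ratio <- v / denom
  fdr <- mean(ratio)
  # delta method: var(mean(v)/mean(d)) ~ var(v - mfdr * d) / (m * mean(d)^2)
  mfdr_se <- if (m > 1)
    stats::sd(v - mfdr * denom) / (sqrt(m) * mean(denom)) else NA_real_
  fdr_se <- if (m > 1) stats::sd(ratio) / sqrt(m) else NA_real_
  list(mfdr = mfdr, fdr = fdr, mfdr_se = mfdr_se, fdr_se = fdr_se, reps = m)
}
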