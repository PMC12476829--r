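# Batch-dependent Gaussian z-test simulator and Monte-Carlo error-rate
# estimators.
#
# Hypotheses arrive in batches of size b. Within a batch the Gaussian noise
# vector is equicorrelated with correlation rho (unit variances); across
# batches everything is independent. Each hypothesis is false (a true
# effect) with probability piA, in which case its z-statistic is shifted by
# +muA (default 3); otherwise it is shifted by muN <= 0, giving (for
# muN < 0) conservative null p-values. H_i: mu_i <= 0 is tested one-sided
# against large z, P_i = 1 - Phi(Z_i).

#' Simulation configuration
#'
#' @param n Number of hypotheses per replication.
#' @param batch_size Batch size `b` (scalar) or a vector of sizes covering
#'   `n` (time-varying batches).
#' @param rho Within-batch equicorrelation in \[0, 1); 0 gives independent
#'   p-values.
#' @param piA Probability that a hypothesis is false (carries an effect).
#' @param muN Mean shift of true-null z-statistics, must be \eqn{\le 0};
#'   negative values give conservative nulls.
#' @param muA Mean shift under the alternative (default 3).
#' @param alpha Nominal overall error level.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n = 100L, batch_size = 10L, rho = 0.5, piA = 0.5,
                       muN = -0.5, muA = 3, alpha = 0.2) {
  if (!is.numeric(rho) || rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(piA) || piA <= 0 || piA >= 1)
    stop("piA must lie in (0, 1)", call. = FALSE)
  if (muN > 0) stop("muN must be <= 0 (conservative or exact nulls)",
                    call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  structure(list(n = as.integer(n), batch_size = as.integer(batch_size),
                 rho = rho, piA = piA, muN = muN, muA = muA, alpha = alpha),
            class = "sim_config")
}

#' Generate one batch-dependent p-value stream
#'
#' Draws one replication of the simulation: equicorrelated Gaussian noise
#' per batch, Bernoulli(`piA`) effect indicators, one-sided upper-tail
#' z-test p-values, and the batch conflict structure.
#'
#' @param cfg A [sim_config()].
#' @param seed Integer seed; identical `(cfg, seed)` pairs give identical
#'   output.
#' @return List with `p` (p-values), `nonnull` (logical, TRUE where the
#'   hypothesis is false, i.e. an effect exists), `z` (test statistics) and
#'   `conflicts` (a lag-representable `conflict_structure`).
#' @export
generate_stream <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(seed)) set.seed(as.integer(seed))
  n <- cfg$n
  b <- cfg$batch_size
  sizes <- if (length(b) == 1L) rep(b, ceiling(n / b)) else b
  if (sum(sizes) < n)
    stop("batch sizes cover only ", sum(sizes), " of ", n, " hypotheses",
         call. = FALSE)
  noise <- numeric(0)
  for (s in sizes) {
    # equicorrelated MVN via a shared factor: sqrt(rho) Z0 + sqrt(1-rho) eps
    z0 <- stats::rnorm(1)
    eps <- stats::rnorm(s)
    noise <- c(noise, sqrt(cfg$rho) * z0 + sqrt(1 - cfg$rho) * eps)
    if (length(noise) >= n) break
  }
  noise <- noise[seq_len(n)]
  nonnull <- stats::runif(n) < cfg$piA
  z <- noise + ifelse(nonnull, cfg$muA, cfg$muN)
  p <- stats::pnorm(z, lower.tail = FALSE)
  list(p = p, nonnull = nonnull, z = z,
       conflicts = batch_conflicts(n, cfg$batch_size))
}

#' Procedure factory for simulations
#'
#' Wraps the testing procedures into a uniform closure
#' `function(p, conflicts) -> logical rejection vector` for use with
#' [estimate_error_rates()] and [power_comparison()].
#'
#' @param tag One of `"graph-conf-u"` (conflict-adjusted uniform-improvement
#'   graph), `"spending"` (local ADDIS-Spending), `"closed-spending"`,
#'   `"graph"` (trivial-conflict graph, ignores conflicts),
#'   `"closed-graph"`, `"bonferroni"`, `"fdr-graph"`, `"uncorrected"`.
#' @param gamma A [make_gamma()] schedule.
#' @param alpha Overall level.
#' @param tau,lam Thresholds (FWER defaults 0.8 / 0.16; pass 0.5 / 0.25 for
#'   the FDR graph).
#' @param w0 Initial wealth for `"fdr-graph"`.
#' @return A function of `(p, conflicts)` returning a logical vector.
#' @export
make_procedure <- function(tag = c("graph-conf-u", "spending",
                                   "closed-spending", "graph", "closed-graph",
                                   "bonferroni", "fdr-graph", "uncorrected"),
                           gamma = make_gamma("quadratic"),
                           alpha = 0.2, tau = 0.8, lam = 0.16,
                           w0 = alpha / 2) {
  tag <- match.arg(tag)
  force(gamma); force(alpha); force(tau); force(lam); force(w0)
  fn <- switch(tag,
    "graph-conf-u" = function(p, conflicts)
      addis_graph_conf(p, gamma, conflicts, "conf_u", alpha, tau, lam)$rejected,
    "spending" = function(p, conflicts)
      addis_spending_local(p, gamma, lags_of(conflicts), alpha, tau,
                           lam)$rejected,
    "closed-spending" = function(p, conflicts)
      closed_addis_spending(p, gamma, lags_of(conflicts), alpha, tau,
                            lam)$rejected,
    "graph" = function(p, conflicts)
      addis_graph(p, gamma, "spending_equivalent", alpha, tau, lam)$rejected,
    "closed-graph" = function(p, conflicts)
      closed_addis_graph_conf(p, gamma, conflicts, "conf_u", alpha, tau,
                              lam)$rejected,
    "bonferroni" = function(p, conflicts)
      online_bonferroni(p, gamma, alpha)$rejected,
    "fdr-graph" = function(p, conflicts)
      fdr_addis_graph(p, gamma, conflicts, alpha = alpha, w0 = w0,
                      tau = tau, lam = lam)$rejected,
    "uncorrected" = function(p, conflicts) p <= alpha
  )
  attr(fn, "tag") <- tag
  fn
}

.rep_seed <- function(seed, rep) {
  (as.integer(seed) + 7919L * rep) %% .Machine$integer.max
}

#' Monte-Carlo error-rate estimates for an online procedure
#'
#' Runs `reps` independent replications of the batch-dependent simulation
#' and estimates: FWER (fraction of replications with at least one false
#' rejection), PFER (mean count of false rejections), and power (mean
#' per-replication proportion of rejected among the false hypotheses;
#' replications without false hypotheses are excluded from the power
#' average, where the proportion is undefined). Binomial / empirical
#' standard errors are attached, and the per-replication counts needed for
#' (m)FDR estimation are returned.
#'
#' @param proc A procedure closure from [make_procedure()] (or any
#'   `function(p, conflicts)` returning a logical rejection vector).
#' @param cfg A [sim_config()].
#' @param reps Number of replications.
#' @param seed Root seed; replications use deterministic per-replication
#'   subseeds, so results do not depend on execution order.
#' @return List with `fwer`, `fwer_se`, `pfer`, `pfer_se`, `power`,
#'   `power_se`, `reps`, and `per_rep` (data frame with columns `v`, `r`,
#'   `n_false`).
#' @export
estimate_error_rates <- function(proc, cfg, reps = 100L, seed = 1L) {
  stopifnot(is.function(proc), inherits(cfg, "sim_config"), reps >= 1)
  v <- r <- n_false <- integer(reps)
  pow <- rep(NA_real_, reps)
  for (k in seq_len(reps)) {
    s <- generate_stream(cfg, seed = .rep_seed(seed, k))
    rej <- proc(s$p, s$conflicts)
    v[k] <- sum(rej & !s$nonnull)
    r[k] <- sum(rej)
    n_false[k] <- sum(s$nonnull)
    if (n_false[k] > 0) pow[k] <- sum(rej & s$nonnull) / n_false[k]
  }
  fwer <- mean(v > 0)
  pow_obs <- pow[!is.na(pow)]
  list(
    fwer = fwer,
    fwer_se = sqrt(fwer * (1 - fwer) / reps),
    pfer = mean(v),
    pfer_se = stats::sd(v) / sqrt(reps),
    power = if (length(pow_obs)) mean(pow_obs) else NA_real_,
    power_se = if (length(pow_obs) > 1)
      stats::sd(pow_obs) / sqrt(length(pow_obs)) else NA_real_,
    reps = reps,
    per_rep = data.frame(v = v, r = r, n_false = n_false)
  )
}

#' Power and FWER comparison across batch sizes
#'
#' Evaluates each procedure on a grid of batch sizes and effect proportions,
#' using the same replicated streams for all procedures within a grid cell
#' (paired comparison).
#'
#' @param cfg Base [sim_config()]; `batch_size` and `piA` are overridden by
#'   the grid.
#' @param procedures Named list of procedure closures
#'   (see [make_procedure()]).
#' @param b_values Batch sizes to evaluate.
#' @param piA_values Effect proportions to evaluate.
#' @param reps Replications per cell.
#' @param seed Root seed.
#' @return Data frame with columns `procedure`, `b`, `piA`, `reps`, `fwer`,
#'   `fwer_se`, `pfer`, `power`, `power_se`.
#' @export
power_comparison <- function(cfg, procedures, b_values = c(1L, 5L, 10L, 20L),
                             piA_values = c(0.2, 0.5), reps = 100L,
                             seed = 1L) {
  stopifnot(length(procedures) >= 1, !is.null(names(procedures)))
  rows <- list()
  for (b in b_values) for (pa in piA_values) {
    cell_cfg <- sim_config(n = cfg$n, batch_size = b, rho = cfg$rho,
                           piA = pa, muN = cfg$muN, muA = cfg$muA,
                           alpha = cfg$alpha)
    # same substream seeds for every procedure: paired estimates
    for (nm in names(procedures)) {
      est <- estimate_error_rates(procedures[[nm]], cell_cfg, reps, seed)
      rows[[length(rows) + 1L]] <- data.frame(
        procedure = nm, b = b, piA = pa, reps = as.integer(reps),
        fwer = est$fwer, fwer_se = est$fwer_se, pfer = est$pfer,
        power = est$power, power_se = est$power_se)
    }
  }
  do.call(rbind, rows)
}

#' Plot a power/FWER comparison table
#'
#' Draws power (solid) and FWER (dashed) against the effect proportion,
#' faceted by batch size, in the style customary for online-testing power
#' studies. Requires ggplot2.
#'
#' @param tbl Output of [power_comparison()].
#' @return A ggplot object.
#' @export
plot_power_comparison <- function(tbl) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("plot_power_comparison requires the ggplot2 package", call. = FALSE)
  long <- rbind(
    data.frame(procedure = tbl$procedure, b = tbl$b, piA = tbl$piA,
               metric = "power", value = tbl$power),
    data.frame(procedure = tbl$procedure, b = tbl$b, piA = tbl$piA,
               metric = "fwer", value = tbl$fwer))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$piA, y = .data$value,
                                     colour = .data$procedure,
                                     linetype = .data$metric)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~b, labeller = ggplot2::label_both) +
    ggplot2::labs(x = expression(pi[A]), y = "power / FWER") +
    ggplot2::theme_minimal()
}
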