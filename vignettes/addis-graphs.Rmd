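---
title: "Adaptive-discarding graphs for online error control"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive-discarding graphs for online error control}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(addisgraph)
```

## The problem

In online multiple testing a stream of hypotheses $H_1, H_2, \ldots$ is
tested one at a time; the individual significance level $\alpha_i$ may use
only information from the past, the total number of hypotheses is unknown,
and an error criterion — familywise error rate (FWER), per-family error
rate (PFER) or false discovery rate (FDR) — must hold at every point of the
stream. Platform trials are the motivating setting: treatment arms enter
and leave an ongoing trial, all compared against a shared control arm.
Concurrent controls make the p-values of *overlapping* arms dependent, and
an arm's level often has to be fixed at entry, before the results of the
arms still running are known. Both constraints are captured by a
*conflict set* $X_i \subseteq \{1, \ldots, i-1\}$: the indices of earlier
hypotheses whose p-values $\alpha_i$ must not use. Conflict sets are
assumed monotone (once an index leaves, it never returns), which holds in
any entry-ordered platform trial. *Local dependence* is the special case
$X_i = \{i-1, \ldots, i-L_i\}$ with lags satisfying $L_{i+1} \le L_i + 1$;
batches of jointly dependent p-values are the special case of that.

## The budget identity and the graph

All FWER procedures here are adaptive-discarding (ADDIS) rules built on the
spend bound

$$\sum_{i=1}^{\infty} \frac{\alpha_i}{\tau_i - \lambda_i}
  \, 1\{\lambda_i < P_i \le \tau_i\} \;\le\; \alpha ,$$

with hyperparameters $0 \le \lambda_i < \tau_i \le 1$. A p-value above
$\tau_i$ is *discarded* as conservative, one at or below $\lambda_i$ is a
rejection *candidate*; in both cases ($U_i = 1$) the scaled level
$\tilde\alpha_i = \alpha_i / (\tau_i - \lambda_i)$ is not charged and can
be handed to later hypotheses. The graph makes this constructive:

$$\tilde\alpha_i \;=\; \alpha\gamma_i \;+\; \sum_{j<i} g_{j,i}\, U_j\,
  \tilde\alpha_j , \qquad \alpha_i = (\tau_i - \lambda_i)\,\tilde\alpha_i,$$

with initial weights $\sum_i \gamma_i \le 1$ and transfer weights
$\sum_{i>j} g_{j,i} \le 1$ per row. Under conflict sets the transfer
weights are additionally zeroed on conflicting pairs
($g^*_{j,i} = 0$ for $j \in X_i$), which keeps $\alpha_i$ measurable with
respect to the permitted history; pathwise the spend bound is unchanged, so
FWER — indeed PFER — control at level $\alpha$ holds under arbitrary
monotone conflict sets. Because rejection uses the inclusive rule
$P_i \le \alpha_i$ and $U_i$ uses inclusive-left/exclusive-right
boundaries, boundary p-values are handled deterministically; a p-value of
exactly 0 is rejected even at level 0.

### Spending, and why the graph dominates it

The local ADDIS-Spending baseline walks the $\gamma$ schedule directly:
$\alpha_i^{spend} = \alpha(\tau_i-\lambda_i)\gamma_{t(i)}$ with
$t(i) = 1 + L_i + \sum_{j \le i - L_i - 1}(1 - U_j)$. Every lagged
predecessor advances the position by one *regardless of its outcome*, so
dependence costs level permanently. `spending_equivalent_weights()` shows
the spending rule is itself a graph with the telescoping weights
$g_{j,i} = (\gamma_{t(j)+i-j-1} - \gamma_{t(j)+i-j})/\gamma_{t(j)}$,
$t(j) = 1 + \sum_{k<j}(1-U_k)$ — a representation that parks transfer mass
on conflicting positions where it can never be used. The
conflict-adjusted weights (`conf_u_weights()`) instead *shift the same
telescoping weights past the conflicting indices*: $g^*_{j,i}$ is the
spending-equivalent weight at the rank of $i$ among $j$'s nonconflicting
successors. No mass is wasted, and the resulting levels dominate the
spending levels at every index on every stream — the package asserts this
on randomized instances rather than only on examples. The construction is
defined for lag structures; for general monotone sets the engine accepts
explicit conflict-adjusted weight tables instead.

On the canonical three-step instance ($\gamma_i = 2^{-i}$, $\tau = 0.8$,
$\lambda = 0.3$, first p-value reusable, second not, conflict
$X_2 = \{1\}$) the three rules give, in units of $\alpha$:

```{r}
g <- make_gamma("geometric", q = 0.5)
p <- c(0.1, 0.5, 0.5)
rbind(
  graph    = addis_graph(p, g, "spending_equivalent", 1e-2, 0.8, 0.3)$level,
  spending = addis_spending_local(p, g, c(0, 1, 0), 1e-2, 0.8, 0.3)$level,
  conf_u   = addis_graph_conf(p, g, conflicts_from_lags(c(0, 1, 0)),
                              "conf_u", 1e-2, 0.8, 0.3)$level) / 1e-2
```

### Closed variants

The closed spending and closed graph rules additionally react to
*rejections*: a rejected predecessor inside the lag window no longer
costs level (`closed_addis_spending()`), and the closed graph forwards
level from nonconflicting predecessors on $\max\{R_j, U_j\}$ and,
optionally, from conflicting ones on rejection via `within_lag` weights
(`closed_addis_graph_conf()`). Two design points follow from the theory
rather than taste. First, in the recommended regime $\lambda_i \ge
\alpha_i$ every rejection is also a candidate, so with the default zero
within-lag weights the closed graph is bit-identical to the plain
conflict graph; the gain only materializes in rejection-driven
configurations such as $\lambda = 0$, $\tau = 1$, where the closed graph
becomes the online analogue of the classical rejection-propagating
graphical procedure. Second, the closed rules inherit FWER control from
the closure principle, not from the spend bound, and can legitimately
exceed it in such configurations; the engines therefore enforce the spend
bound as a hard error (tolerance $10^{-10}$) only for the condition-bound
procedures and keep it informational for the closed ones.

### FDR graph

`fdr_addis_graph()` starts from wealth $W_0 \le \alpha$ and adds
rejection-triggered gains along a second weight family $h^*$ with the same
constraints as $g^*$: the first rejection releases $\alpha - W_0$ (topping
the stream back up to $\alpha$), every later one a full $\alpha$. We read
the first-rejection convention this way because it is the standard
generalized alpha-investing accounting — no net gain for the rejection
that merely restores the hold-back — and it makes the no-rejection stream
collapse exactly onto the FWER graph at level $W_0$, which the tests
assert. Defaults: $W_0 = \alpha/2$ (a configurable half-split convention;
no canonical value exists), $h^* = g^*$, $\tau = 0.5$, $\lambda = 0.25$.
The guarantee is mFDR control in general and FDR control under
independence; both estimators are reported by `estimate_mfdr()`, with a
delta-method standard error for the mFDR ratio.

## Tunable parameters

* `alpha` — the controlled error level (probability units). FWER examples
  here use 0.2 for simulation visibility and 0.05 in trial-sized examples.
* `tau`, `lam` — discarding and candidate thresholds. Defaults 0.8 / 0.16
  for FWER, 0.5 / 0.25 for FDR; ADDIS rules are robust for
  $\lambda \gtrsim 0.1$ and $\tau \lesssim 0.9$. For $\tau_i < 1$ the null
  p-values must be uniformly valid
  ($P(P_i \le xy \mid P_i \le y) \le x$) — this is assumed, not checked at
  run time, as it cannot be verified from a single realization.
* `gamma` — the initial-weight schedule. Geometric
  ($\gamma_i = q^{i-1}(1-q)$; worst-case proportion spent after $i$ steps
  is exactly $1 - q^i$, making $q$ directly interpretable), quadratic
  ($6/(\pi^2 i^2)$), and horizon-normalized $1/((i{+}1)\log^2(i{+}1))$ and
  $i^{-s}$ families. Families without a closed-form sum are normalized
  over a finite horizon (default 10\,000) and the tail mass beyond it is
  simply never spent — the budget inequality only requires
  $\sum\gamma_i \le 1$.
* transfer weights — schedule-derived (`spending_equivalent`, `conf_u`),
  fixed geometric rows, explicit CSV tables, or a history callback
  `function(j, i, u)`; callbacks receive only the reuse indicators, the
  information the weights are allowed to depend on. Row sums and
  nonnegativity are validated as the stream progresses (tolerance
  $10^{-12}$, pure floating-point slack).

## The synthetic generator

`generate_stream()` draws the batch-dependent Gaussian study:
$n = 100$ hypotheses in batches of size $b$, within-batch equicorrelated
noise (correlation $\rho$, via a shared-factor construction), a hypothesis
false with probability $\pi_A$ (z-shift $+3$) and otherwise a conservative
null (shift $\mu_N \le 0$), one-sided upper-tail z-test p-values
$P_i = 1 - \Phi(Z_i)$. The upper tail is the only convention consistent
with testing $H_i: \mu_i \le 0$ against positive shifts. Defaults
$\rho = 0.5$, $\mu_N = -0.5$, $\alpha = 0.2$ are the study conditions the
Monte-Carlo tests run under. Replications use deterministic
per-replication subseeds from one root seed, so estimates do not depend on
execution order.

What the generator does *not* emulate: heavy-tailed or misspecified test
statistics, dependence across batches, time-varying effect sizes, and the
actual shared-control-arm mechanics of a platform trial (conflicts are
taken as given, not derived from patient overlap). Passing Monte-Carlo
tests therefore demonstrate error control under equicorrelated Gaussian
batch dependence with conservative nulls — the conflict-set machinery is
exercised exactly, but real-data robustness beyond this model is not
tested.

Conventions in `estimate_error_rates()`: FWER is the fraction of
replications with at least one false rejection, PFER the mean count, and
power the mean per-replication proportion of rejected among false
hypotheses, with replications containing no false hypothesis excluded
(the proportion is undefined there). Monte-Carlo sizes used by the test
suite — 250–1000 streams for pathwise properties, 300 replications per
simulation cell, 1000 for the mFDR check, 500 for the headline FWER
estimate in `scripts/acceptance.R` — keep standard errors around 0.01–0.02
on probability scales, small against the margins being tested.

## Numerical and degenerate-input choices

* Weight-sum and schedule checks use absolute tolerance $10^{-12}$; the
  spend bound uses $10^{-10}$; equivalence assertions (graph vs. spending)
  hold to $10^{-10}$ on arbitrary streams.
* Recursive closed levels are evaluated strictly forward; $R_j$ is fixed
  when $H_j$ is tested and never revised.
* A level can be exactly 0 once a finite schedule is exhausted; by the
  inclusive rule it still rejects $P_i = 0$.
* `remaining_budget()` uses closed-form tails where the schedule admits
  them (geometric $q^n$, quadratic via the trigamma function, telescoping
  transfer rows) and horizon truncation otherwise; future hypotheses are
  taken as nonconflicting with the tested ones, matching the convention of
  quoting the remaining level as a Bonferroni continuation.
* Timeline overlap is closed-interval: touching intervals conflict. The
  doubtful case costs power, never validity.
* All user-facing indices are 1-based; CSV output carries 12 significant
  digits.

## Limitations

The correlation-exploiting refinement that uses the known joint
distribution of within-batch p-values is out of scope, as is any
re-optimization of past levels or estimation of the true-null proportion.
The uniform-improvement weight construction is proved-by-property for lag
structures only; general monotone conflict sets require user-supplied
conflict-adjusted tables. The FDR graph's superiority over other adaptive
FDR algorithms is plausible for the same reasons as in the FWER case but
is not a proven uniform improvement, and is not claimed as one.
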