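# Monotone conflict sets.
#
# X_i collects the indices j < i of earlier hypotheses on whose p-values the
# level alpha_i must not depend -- because P_j and P_i are dependent (shared
# control data, batches) or because H_i's level had to be fixed before P_j
# was observed (asynchronous testing). Monotone means: once j stops
# conflicting (j not in X_i for some i > j), it never conflicts again.

#' Conflict structure
#'
#' Low-level constructor; most users should use [conflicts_from_lags()],
#' [batch_conflicts()] or [conflicts_from_timeline()].
#'
#' @param sets List of integer vectors; element `i` is \eqn{X_i \subseteq
#'   \{1, \ldots, i-1\}}. Indices beyond `length(sets)` are taken to have
#'   empty conflict sets.
#' @return An object of class `conflict_structure` with fields `sets`,
#'   `lags` (integer lags when every set is a contiguous suffix
#'   \eqn{\{i-1,\ldots,i-L_i\}}, else `NULL`) and `n`.
#' @export
conflict_structure <- function(sets) {
  stopifnot(is.list(sets))
  n <- length(sets)
  sets <- lapply(seq_len(n), function(i) {
    x <- sort(unique(as.integer(sets[[i]])))
    if (length(x) && (min(x) < 1L || max(x) >= i))
      stop("conflict set X_", i, " must be a subset of {1, ..., ", i - 1, "}",
           call. = FALSE)
    x
  })
  # monotonicity: j not in X_i (for some i > j) implies j not in X_k, k >= i
  for (j in seq_len(n)) {
    released <- FALSE
    for (i in seq_len(n)) {
      if (i <= j) next
      inset <- j %in% sets[[i]]
      if (!inset) released <- TRUE
      if (inset && released)
        stop("conflict sets are not monotone: index ", j,
             " re-enters the conflict set X_", i, call. = FALSE)
    }
  }
  lags <- .lags_if_representable(sets)
  structure(list(sets = sets, lags = lags, n = n),
            class = "conflict_structure")
}

.lags_if_representable <- function(sets) {
  n <- length(sets)
  lags <- integer(n)
  for (i in seq_len(n)) {
    x <- sets[[i]]
    L <- length(x)
    if (L > 0 && !identical(x, (i - L):(i - 1L))) return(NULL)
    lags[i] <- L
  }
  lags
}

#' Conflict sets from lags (local dependence)
#'
#' Local dependence with lags \eqn{L_i} means \eqn{P_i} is independent of
#' all p-values more than \eqn{L_i} steps back; the induced conflict sets
#' are the contiguous suffixes \eqn{X_i = \{i-1, \ldots, i-L_i\}}. The lag
#' growth condition \eqn{L_{i+1} \le L_i + 1} guarantees monotonicity.
#'
#' @param lags Integer vector of nonnegative lags with `lags[i] <= i - 1`.
#' @return A `conflict_structure`.
#' @examples
#' conflicts_from_lags(c(0, 1, 0))   # X_2 = {1}, others empty
#' @export
conflicts_from_lags <- function(lags) {
  lags <- as.integer(lags)
  n <- length(lags)
  if (any(lags < 0)) stop("lags must be nonnegative", call. = FALSE)
  if (any(lags > seq_len(n) - 1L))
    stop("lag exceeds number of earlier hypotheses at index ",
         which(lags > seq_len(n) - 1L)[1], call. = FALSE)
  if (n > 1) {
    bad <- which(lags[-1] > lags[-n] + 1L)
    if (length(bad))
      stop("lag growth violation at index ", bad[1] + 1L,
           ": L_{i+1} <= L_i + 1 is required for monotone conflict sets",
           call. = FALSE)
  }
  sets <- lapply(seq_len(n), function(i)
    if (lags[i] > 0) (i - lags[i]):(i - 1L) else integer(0))
  structure(list(sets = sets, lags = lags, n = n),
            class = "conflict_structure")
}

#' Batch conflict sets
#'
#' P-values arriving in disjoint batches depend on each other within a batch
#' and are independent across batches. Earlier members of a hypothesis's own
#' batch form its conflict set, equivalently lags equal to the within-batch
#' position minus one.
#'
#' @param n Number of hypotheses.
#' @param batch_sizes Positive batch sizes; recycled pattern must cover `n`
#'   (a single number gives constant batches).
#' @return A `conflict_structure` (lag-representable).
#' @examples
#' batch_conflicts(4, c(2, 2))   # X_2 = {1}, X_4 = {3}
#' @export
batch_conflicts <- function(n, batch_sizes) {
  n <- as.integer(n)
  b <- as.integer(batch_sizes)
  if (any(b < 1)) stop("batch sizes must be positive", call. = FALSE)
  if (length(b) == 1L) b <- rep(b, ceiling(n / b))
  if (sum(b) < n)
    stop("batch sizes cover only ", sum(b), " of ", n, " hypotheses",
         call. = FALSE)
  pos <- unlist(lapply(b, seq_len))[seq_len(n)]
  conflicts_from_lags(pos - 1L)
}

#' Trial timeline
#'
#' Ordered record of treatment-arm activity intervals in a platform trial.
#' Arms must be ordered by entry time; with concurrent controls, overlapping
#' arms share control data and therefore conflict.
#'
#' @param arm_id Arm identifiers (unique).
#' @param entry,exit Numeric entry and exit times, `entry < exit` per arm.
#' @return An object of class `trial_timeline` (a data frame).
#' @export
trial_timeline <- function(arm_id, entry, exit) {
  stopifnot(length(arm_id) == length(entry), length(entry) == length(exit))
  if (anyDuplicated(arm_id)) stop("arm_id must be unique", call. = FALSE)
  if (any(entry >= exit))
    stop("each arm requires entry < exit", call. = FALSE)
  if (is.unsorted(entry))
    stop("arms must be ordered by entry time; sort the timeline by 'entry' ",
         "before constructing it", call. = FALSE)
  structure(data.frame(arm_id = arm_id, entry = entry, exit = exit),
            class = c("trial_timeline", "data.frame"))
}

#' Conflict sets from a platform-trial timeline
#'
#' Arm `j` conflicts with a later arm `i` when their activity intervals
#' overlap (closed intervals: touching endpoints count as overlap, the
#' conservative reading -- a doubtful case is declared a conflict, which can
#' forgo power but never validity). With arms ordered by entry time the
#' induced conflict sets are monotone; this is asserted.
#'
#' @param timeline A [trial_timeline()] (or data frame with columns
#'   `arm_id`, `entry`, `exit`, ordered by entry).
#' @return A `conflict_structure`; overlap patterns that defeat a lag
#'   representation are kept as explicit sets.
#' @export
conflicts_from_timeline <- function(timeline) {
  if (!inherits(timeline, "trial_timeline"))
    timeline <- trial_timeline(timeline$arm_id, timeline$entry, timeline$exit)
  n <- nrow(timeline)
  sets <- lapply(seq_len(n), function(i) {
    js <- seq_len(i - 1L)
    js[timeline$exit[js] >= timeline$entry[i] &
       timeline$entry[js] <= timeline$exit[i]]
  })
  conflict_structure(sets)
}

#' Lags of a lag-representable conflict structure
#'
#' @param conflicts A `conflict_structure`.
#' @return Integer lag vector, or an error when the sets are not contiguous
#'   suffixes.
#' @export
lags_of <- function(conflicts) {
  stopifnot(inherits(conflicts, "conflict_structure"))
  if (is.null(conflicts$lags))
    stop("conflict structure is not lag-representable", call. = FALSE)
  conflicts$lags
}

#' @export
print.conflict_structure <- function(x, ...) {
  cat("<conflict_structure> n =", x$n,
      if (!is.null(x$lags)) paste0("(lag-representable, max lag ",
                                   max(c(0L, x$lags)), ")") else
        "(general monotone sets)", "\n")
  invisible(x)
}
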