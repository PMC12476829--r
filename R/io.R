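# CSV readers/writers and the flat-key run configuration.
#
# All indices in files are 1-based; floating-point output uses 12
# significant digits; files are UTF-8 comma-separated with a mandatory
# header row.

#' Read a p-value table
#'
#' Expects a header and columns `index`, `p_value`, with optional per-index
#' `tau` and `lam` overrides.
#'
#' @param path CSV file path.
#' @return Data frame with columns `index`, `p_value` and, when present,
#'   `tau`, `lam`, ordered by `index`.
#' @export
read_pvalue_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("index", "p_value") %in% names(df)))
    stop("p-value table requires columns 'index' and 'p_value'",
         call. = FALSE)
  bad <- which(!is.finite(df$p_value) | df$p_value < 0 | df$p_value > 1)
  if (length(bad))
    stop("p-value outside [0, 1] in row ", bad[1], " of ", path,
         call. = FALSE)
  if ("tau" %in% names(df) || "lam" %in% names(df)) {
    tau <- if ("tau" %in% names(df)) df$tau else 0.8
    lam <- if ("lam" %in% names(df)) df$lam else 0.16
    if (any(lam >= tau) || any(lam < 0) || any(tau > 1))
      stop("per-index hyperparameters must satisfy 0 <= lam < tau <= 1",
           call. = FALSE)
  }
  df[order(df$index), , drop = FALSE]
}

#' Write a decisions table
#'
#' Writes one row per tested hypothesis: `index`, `level`, `scaled_level`,
#' `u`, `rejected`, `spent_so_far`, `remaining_budget` (the level still
#' available to future hypotheses after this step).
#'
#' @param result An `addis_result`.
#' @param path Output CSV path.
#' @return Invisibly, the written data frame.
#' @export
write_decisions <- function(result, path) {
  stopifnot(inherits(result, "addis_result"))
  n <- nrow(result)
  rem <- vapply(seq_len(n), function(i)
    remaining_budget(result[seq_len(i), , drop = FALSE] |>
                       .restore_result_attrs(result, i)),
    numeric(1))
  out <- data.frame(
    index = result$index,
    level = signif(result$level, 12),
    scaled_level = signif(result$scaled_level, 12),
    u = result$u,
    rejected = result$rejected,
    spent_so_far = signif(result$spent_so_far, 12),
    remaining_budget = signif(rem, 12))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}

# subsetting an addis_result drops its attributes; rebuild a prefix view
.restore_result_attrs <- function(df, full, i) {
  structure(df, class = c("addis_result", "data.frame"),
            procedure = attr(full, "procedure"),
            alpha = attr(full, "alpha"),
            gamma = attr(full, "gamma"),
            transfer_kind = attr(full, "transfer_kind"),
            transfer = attr(full, "transfer"),
            lags = attr(full, "lags")[seq_len(i)],
            tj = attr(full, "tj")[seq_len(i)],
            cnt = .cnt_prefix(attr(full, "lags"), i, nrow(full)),
            at = attr(full, "at")[seq_len(i)],
            u = attr(full, "u")[seq_len(i)])
}

# nonconflicting-successor counts as they stood after step i
.cnt_prefix <- function(lags, i, n) {
  if (is.null(lags)) lags <- integer(n)
  vapply(seq_len(i), function(j)
    if (i > j) rank_count(j, i, lags) else 0L, integer(1))
}

#' Read a lag table
#'
#' Columns `i`, `lag`; returns the induced conflict structure.
#' @param path CSV file path.
#' @return A `conflict_structure`.
#' @export
read_lag_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("i", "lag") %in% names(df)))
    stop("lag table requires columns 'i' and 'lag'", call. = FALSE)
  df <- df[order(df$i), ]
  conflicts_from_lags(df$lag)
}

#' Read explicit conflict pairs
#'
#' Columns `i`, `j`, one conflicting pair per row (`j < i`).
#' @param path CSV file path.
#' @return A `conflict_structure`.
#' @export
read_conflict_pairs <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("i", "j") %in% names(df)))
    stop("conflict-pair table requires columns 'i' and 'j'", call. = FALSE)
  n <- max(df$i, 0)
  sets <- lapply(seq_len(n), function(i) df$j[df$i == i])
  conflict_structure(sets)
}

#' Read a trial timeline
#'
#' Columns `arm_id`, `entry`, `exit`; rows are sorted by entry time before
#' construction.
#' @param path CSV file path.
#' @return A `trial_timeline`.
#' @export
read_timeline_csv <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("arm_id", "entry", "exit") %in% names(df)))
    stop("timeline requires columns 'arm_id', 'entry', 'exit'",
         call. = FALSE)
  df <- df[order(df$entry), ]
  trial_timeline(df$arm_id, df$entry, df$exit)
}

#' Read a flat run configuration
#'
#' One `key = value` pair per line, keys as dotted paths (e.g.
#' `gamma.family = geometric`), `#` starts a comment. Values are parsed as
#' numbers when possible.
#'
#' @param path Config file path.
#' @return Named list of values.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop("config not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    if (!grepl("=", ln, fixed = TRUE))
      stop("malformed config line (expected key = value): ", ln,
           call. = FALSE)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

cfg_get <- function(cfg, key, default = NULL) {
  if (!is.null(cfg[[key]])) cfg[[key]] else default
}

# build a gamma schedule from config keys gamma.family / gamma.q /
# gamma.exponent / gamma.horizon
gamma_from_config <- function(cfg) {
  make_gamma(
    family = cfg_get(cfg, "gamma.family", "geometric"),
    q = cfg_get(cfg, "gamma.q", 0.5),
    exponent = cfg_get(cfg, "gamma.exponent", 1.6),
    horizon = cfg_get(cfg, "gamma.horizon", 10000L))
}
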