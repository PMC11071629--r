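#' Split trials into latency groups
#'
#' Orders trials by saccade reaction time (ties broken by input order) and
#' partitions them into `n_groups` contiguous blocks of near-equal size,
#' Group 1 holding the shortest latencies. When the trial count is not a
#' multiple of `n_groups`, the remainder goes to the earliest groups.
#'
#' @param rt Numeric vector of reaction times (NA trials are left
#'   unassigned).
#' @param n_groups Number of groups.
#' @return Integer vector of group indices (same length as `rt`; `NA`
#'   where `rt` is `NA`).
#' @export
split_by_latency <- function(rt, n_groups = 4) {
  ok <- which(!is.na(rt))
  if (length(ok) < n_groups) {
    stop("fewer trials with RT than groups")
  }
  n <- length(ok)
  base <- n %/% n_groups
  sizes <- rep(base, n_groups) + (seq_len(n_groups) <= n %% n_groups)
  ord <- ok[order(rt[ok])]          # stable: ties keep input order
  groups <- rep(NA_integer_, length(rt))
  groups[ord] <- rep(seq_len(n_groups), times = sizes)
  groups
}

#' Correlation between latency-group order and activity
#'
#' Pearson correlation of the group indices (1..k) with the group-mean
#' activities. Zero variance in the means makes the correlation undefined
#' (`NA` with attribute `degenerate`).
#'
#' @param group_means Numeric vector of per-group mean activities, ordered
#'   from the shortest-latency group upward.
#' @return Correlation coefficient in `[-1, 1]`, or flagged `NA`.
#' @export
latency_activity_correlation <- function(group_means) {
  if (any(!is.finite(group_means))) stop("group means must be finite")
  if (sd(group_means) == 0) {
    return(structure(NA_real_, degenerate = TRUE))
  }
  cor(seq_along(group_means), group_means)
}

#' Wilcoxon signed-rank test of the median correlation
#'
#' Tests whether the median of per-neuron latency-activity correlation
#' coefficients differs from zero (two-sided). Exact signed-rank p for
#' n <= 25 without ties or zeros; the normal approximation with tie and
#' zero handling otherwise.
#'
#' @param rs Numeric vector of per-neuron correlations (`NA`s dropped).
#' @return List with `median`, `p`, `n`.
#' @export
median_r_test <- function(rs) {
  rs <- rs[!is.na(rs)]
  if (length(rs) < 6) stop("need at least 6 defined correlations")
  nonzero <- rs[rs != 0]
  if (length(nonzero) == 0L) {
    return(list(median = 0, p = 1, n = length(rs)))
  }
  exact <- length(nonzero) <= 25 && !any(duplicated(abs(nonzero)))
  ht <- suppressWarnings(wilcox.test(rs, mu = 0, exact = exact,
                                     correct = !exact))
  list(median = median(rs), p = ht$p.value, n = length(rs))
}

#' Per-neuron latency-activity correlation analysis
#'
#' For each session (neuron) and each (value, direction) condition with
#' enough reaction times: split trials into latency quartiles, average the
#' Z-scored window activity per group, and correlate group order with mean
#' activity. Condition-wise medians are then tested against zero with the
#' signed-rank test.
#'
#' @param sessions List of choice-task `ephys_session`s.
#' @param window Analysis window, ms post target onset.
#' @param n_groups Number of latency groups.
#' @param min_trials Minimum RT trials per condition.
#' @return List with `per_neuron` (data frame: neuron, condition, r and
#'   group means) and `tests` (per condition: median r, Wilcoxon p, n).
#' @export
latency_correlation_analysis <- function(sessions, window = c(100, 300),
                                         n_groups = 4, min_trials = 8) {
  rows <- list()
  for (s in sessions) {
    tr <- s$trials
    usable <- !is.na(tr$t_target_ms) & !is.na(tr$rt_ms)
    act <- trial_window_activity(s$spikes, tr$t_target_ms[usable],
                                 window = window)
    if (act$baseline$degenerate) next
    sub <- tr[usable, ]
    key <- paste(sub$value, sub$direction, sep = ".")
    for (cond in unique(key)) {
      sel <- key == cond
      if (sum(sel) < max(min_trials, n_groups)) next
      grp <- split_by_latency(sub$rt_ms[sel], n_groups)
      gm <- tapply(act$z[sel], grp, mean)
      r <- latency_activity_correlation(as.numeric(gm))
      rows[[length(rows) + 1L]] <- data.frame(
        neuron_id = paste(s$monkey_id, s$neuron_id, sep = "_"),
        condition = cond, r = as.numeric(r),
        degenerate = isTRUE(attr(r, "degenerate")),
        t(setNames(as.numeric(gm), paste0("g", seq_len(n_groups)))),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) stop("no usable neuron-conditions")
  per_neuron <- do.call(rbind, rows)
  rownames(per_neuron) <- NULL
  tests <- lapply(split(per_neuron, per_neuron$condition), function(g) {
    rs <- g$r[!g$degenerate]
    if (length(rs) >= 6) {
      res <- median_r_test(rs)
      data.frame(condition = g$condition[1], n = res$n,
                 median_r = res$median, p = res$p)
    } else {
      data.frame(condition = g$condition[1], n = length(rs),
                 median_r = if (length(rs)) median(rs) else NA_real_,
                 p = NA_real_)
    }
  })
  tests <- do.call(rbind, tests)
  rownames(tests) <- NULL
  list(per_neuron = per_neuron, tests = tests)
}
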