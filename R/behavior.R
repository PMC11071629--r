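#' Two-dimensional eye speed by central differences
#'
#' Speed in deg/s at each sample of a 1-kHz eye trace, estimated by the
#' central finite difference over the raw 1-ms samples (no pre-smoothing).
#' End samples get speed 0.
#'
#' @param eye An `eye_trace` (uniform 1-ms sampling).
#' @return Numeric vector of speeds, one per sample.
#' @export
eye_speed <- function(eye) {
  n <- nrow(eye)
  if (n < 3) return(rep(0, n))
  if (any(diff(eye$t_ms) != 1)) stop("eye trace must be uniformly sampled at 1 ms")
  vx <- (eye$x_deg[3:n] - eye$x_deg[1:(n - 2)]) / 2
  vy <- (eye$y_deg[3:n] - eye$y_deg[1:(n - 2)]) / 2
  c(0, sqrt(vx^2 + vy^2) * 1000, 0)
}

eye_index <- function(eye, t) {
  i <- t - eye$t_ms[1] + 1
  if (any(i < 1 | i > nrow(eye), na.rm = TRUE)) {
    stop("requested time outside the eye trace span")
  }
  i
}

#' Detect a saccade by velocity threshold
#'
#' Returns the first time within `search_window` ms of the reference event
#' at which the 2D eye speed (central finite difference over raw 1-ms
#' samples) exceeds `threshold` deg/s, or `NA` if the speed never crosses
#' the threshold in the window.
#'
#' @param eye An `eye_trace` covering the search window.
#' @param t_ref Reference time, ms (typically target onset).
#' @param search_window Window length after `t_ref`, ms.
#' @param threshold Speed threshold, deg/s.
#' @return Saccade onset time in ms, or `NA_real_`.
#' @export
detect_saccade <- function(eye, t_ref, search_window = 400, threshold = 40) {
  i0 <- eye_index(eye, floor(t_ref))
  i1 <- eye_index(eye, floor(t_ref + search_window))
  speed <- eye_speed(eye)
  idx <- which(speed[i0:i1] > threshold)
  if (length(idx) == 0L) return(NA_real_)
  eye$t_ms[i0 + idx[1] - 1]
}

in_square <- function(x, y, center, halfwidth) {
  abs(x - center[1]) <= halfwidth & abs(y - center[2]) <= halfwidth
}

#' Classify the action taken in a trial
#'
#' Reconstructs the behavioral outcome of one trial from the eye trace and
#' the trial geometry:
#'
#' * `FixBreak` -- a supra-threshold saccade leaves the central fixation
#'   zone before target onset (choice task) or toward the object during an
#'   object display (fixation task);
#' * `Stay` -- no saccade is detected within `search_window` of target
#'   onset and gaze remains inside the central zone for the decision
#'   window;
#' * `Accept` -- gaze enters the square target window and remains inside
#'   for at least `accept_hold` ms;
#' * `Return` -- gaze enters the target window, exits in under
#'   `accept_hold` ms, and comes back within `center_radius` of the center;
#' * `Other` -- a saccade lands outside the target window (or leaves it)
#'   without a timely return to center.
#'
#' @param eye An `eye_trace`.
#' @param target_xy Length-2 target center, degrees.
#' @param t_target Target onset, ms (`NA` allowed for aborted trials).
#' @param t_fp Fixation-point onset, ms; enables fixation-break detection
#'   before target onset.
#' @param task `"choice"` or `"fixation"`.
#' @param accept_hold Hold duration that converts a target fixation into an
#'   acceptance, ms.
#' @param target_halfwidth Half-width of the square target window, degrees.
#' @param center_radius Radius of the central fixation zone, degrees.
#' @param decision_window Post-target window over which Stay/Return are
#'   adjudicated, ms.
#' @param search_window,threshold Passed to [detect_saccade()].
#' @return One of `"Accept"`, `"Return"`, `"Stay"`, `"Other"`, `"FixBreak"`.
#' @export
classify_action <- function(eye, target_xy, t_target, t_fp = NULL,
                            task = "choice", accept_hold = 400,
                            target_halfwidth = 4, center_radius = 4,
                            decision_window = 1000, search_window = 400,
                            threshold = 40) {
  if (is.null(target_xy) && !is.na(t_target)) {
    stop("trial geometry (target position) is required")
  }
  speed <- eye_speed(eye)
  r_center <- sqrt(eye$x_deg^2 + eye$y_deg^2)
  if (task == "fixation") {
    # any supra-threshold saccade leaving fixation during the object span
    if (!is.null(t_fp) && !is.na(t_target)) {
      i0 <- eye_index(eye, floor(t_target))
      i1 <- min(nrow(eye), eye_index(eye, floor(t_target)) + 4000)
      brk <- which(speed[i0:i1] > threshold & r_center[i0:i1] > center_radius)
      return(if (length(brk)) "FixBreak" else "Stay")
    }
    return("Stay")
  }
  # pre-target fixation break
  if (!is.null(t_fp)) {
    fp_end <- if (is.na(t_target)) min(max(eye$t_ms), t_fp + 700) else t_target
    i0 <- eye_index(eye, ceiling(t_fp))
    i1 <- eye_index(eye, floor(fp_end))
    if (i1 > i0) {
      brk <- which(speed[i0:i1] > threshold & r_center[i0:i1] > center_radius)
      if (length(brk)) return("FixBreak")
    }
  }
  if (is.na(t_target)) return("FixBreak")
  # action adjudication spans the decision window; the shorter
  # `search_window` is the reaction-time detection criterion only
  onset <- detect_saccade(eye, t_target,
                          min(decision_window,
                              max(eye$t_ms) - t_target - 1), threshold)
  if (is.na(onset)) return("Stay")
  i_on <- eye_index(eye, floor(onset))
  i_end <- min(nrow(eye), eye_index(eye, floor(t_target)) + decision_window)
  idx <- i_on:i_end
  inside <- in_square(eye$x_deg[idx], eye$y_deg[idx], target_xy,
                      target_halfwidth)
  entry <- which(inside)[1]
  if (is.na(entry)) return("Other")
  exit_rel <- which(!inside[entry:length(idx)])[1]
  if (is.na(exit_rel) || exit_rel - 1 >= accept_hold) return("Accept")
  after <- idx[entry + exit_rel - 1]:i_end
  back <- any(r_center[after] <= center_radius)
  if (back) "Return" else "Other"
}

#' Classify every trial of a session
#'
#' Applies [classify_action()] to each trial of a session with an eye
#' trace, using the session's task geometry.
#'
#' @param session An `ephys_session` with a non-`NULL` eye trace.
#' @param ... Passed to [classify_action()].
#' @return Character vector of action labels, one per trial.
#' @export
classify_session_actions <- function(session, ...) {
  if (is.null(session$eye)) stop("session has no eye trace")
  task <- session$config
  vapply(seq_len(nrow(session$trials)), function(i) {
    tr <- session$trials[i, ]
    classify_action(session$eye,
                    target_position(tr$angle_deg,
                                    task$target_eccentricity_deg),
                    tr$t_target_ms, t_fp = tr$t_fp_ms,
                    task = session$task,
                    accept_hold = task$accept_hold_ms,
                    target_halfwidth = task$target_halfwidth_deg, ...)
  }, character(1))
}

round_half_up <- function(x, digits = 1) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Expand an action-count table into trial records
#'
#' Turns a per-(monkey, scene) count table (as returned by
#' [action_count_table()]) into one minimal bad-object trial record per
#' counted action, so that count-level fixtures can flow through the same
#' summary path as classified trials.
#'
#' @param counts Data frame with columns `monkey`, `scene` and action counts
#'   `Accept`, `Return`, `Stay`, `Other`, `FixBreak`.
#' @return Data frame with columns `monkey_id`, `scene`, `value`, `action`.
#' @export
expand_action_counts <- function(counts) {
  actions <- c("Accept", "Return", "Stay", "Other", "FixBreak")
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    n <- as.integer(counts[i, actions])
    data.frame(monkey_id = counts$monkey[i], scene = counts$scene[i],
               value = "bad", action = rep(actions, n),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$action <- factor(out$action, levels = actions)
  out
}

#' Summarize chosen actions for bad objects
#'
#' Counts and percentages of each action among bad-object trials, per
#' monkey and scene, plus pooled non-switch (scenes 1-2) and switch
#' (scenes 3-4) rows. The percentage denominator is all bad-object trials
#' of the row (fixation breaks included); percentages are rounded half-up
#' to one decimal. Optionally also summarizes reaction times per (monkey,
#' scene, value).
#'
#' @param trials Data frame with columns `monkey_id`, `scene`, `value`,
#'   `action`, and optionally `rt_ms`.
#' @return A list of class `behavior_summary` with elements
#'   `action_counts` (counts and `pct_*` columns) and `rt_stats` (or
#'   `NULL` when `rt_ms` is absent).
#' @export
summarize_actions <- function(trials) {
  actions <- c("Accept", "Return", "Stay", "Other", "FixBreak")
  bad <- trials[trials$value == "bad", , drop = FALSE]
  count_block <- function(sub, scene_label) {
    tab <- table(factor(sub$action, levels = actions))
    total <- sum(tab)
    row <- data.frame(monkey = sub$monkey_id[1],
                      scene = scene_label, total = total)
    for (a in actions) row[[a]] <- as.integer(tab[[a]])
    for (a in actions) {
      row[[paste0("pct_", a)]] <-
        if (total > 0) round_half_up(100 * tab[[a]] / total, 1) else NA_real_
    }
    row
  }
  blocks <- list()
  for (m in sort(unique(bad$monkey_id))) {
    bm <- bad[bad$monkey_id == m, ]
    for (sc in sort(unique(bm$scene))) {
      blocks[[length(blocks) + 1L]] <-
        count_block(bm[bm$scene == sc, ], as.character(sc))
    }
    for (pool in list(c("nonswitch", 1, 2), c("switch", 3, 4))) {
      sub <- bm[bm$scene %in% as.numeric(pool[2:3]), ]
      if (nrow(sub)) {
        blocks[[length(blocks) + 1L]] <- count_block(sub, pool[1])
      }
    }
  }
  counts <- do.call(rbind, blocks)
  rownames(counts) <- NULL
  rt_stats <- NULL
  if ("rt_ms" %in% names(trials)) {
    with_rt <- trials[!is.na(trials$rt_ms), , drop = FALSE]
    # bad-object RTs: return-go saccades only
    with_rt <- with_rt[with_rt$value == "good" |
                         with_rt$action == "Return", , drop = FALSE]
    if (nrow(with_rt)) {
      grp <- interaction(with_rt$monkey_id, with_rt$scene, with_rt$value,
                         drop = TRUE)
      rt_stats <- do.call(rbind, lapply(split(with_rt, grp), function(g) {
        n <- nrow(g); m <- mean(g$rt_ms); s <- sd(g$rt_ms)
        half <- if (n > 1) qt(0.975, n - 1) * s / sqrt(n) else NA_real_
        data.frame(monkey = g$monkey_id[1], scene = g$scene[1],
                   value = g$value[1], n = n, mean_rt_ms = m, sd_ms = s,
                   ci_lo = m - half, ci_hi = m + half)
      }))
      rownames(rt_stats) <- NULL
    }
  }
  structure(list(action_counts = counts, rt_stats = rt_stats),
            class = "behavior_summary")
}

#' Welch's unequal-variance t test on reaction times
#'
#' Compares good-object and bad-object saccade reaction times with Welch's
#' t statistic and Welch-Satterthwaite degrees of freedom (two-sided).
#' Bad-object samples should contain return-go saccades only.
#'
#' @param rt_good,rt_bad Numeric vectors of reaction times, ms (n >= 2 each).
#' @return List with `t`, `df`, `p`, per-group `means`, `sds`, `n`, and the
#'   95% CI of the mean difference.
#' @export
compare_rt_welch <- function(rt_good, rt_bad) {
  if (length(rt_good) < 2 || length(rt_bad) < 2) {
    stop("each sample needs at least two reaction times")
  }
  ht <- t.test(rt_good, rt_bad, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value,
       means = c(good = mean(rt_good), bad = mean(rt_bad)),
       sds = c(good = sd(rt_good), bad = sd(rt_bad)),
       n = c(good = length(rt_good), bad = length(rt_bad)),
       ci = unname(ht$conf.int))
}

#' Fisher's exact test and phi for stay proportions
#'
#' Tests whether the proportion of Stay rejections differs between the
#' value-stable (non-switch) and value-swapped (switch) scene pairs.
#' The primary table construction is Stay versus Return; the alternative
#' pools all non-Stay rejections (`mode = "stay-vs-all"`).
#'
#' @param counts_nonswitch,counts_switch Length-2 integer vectors
#'   `c(stay, other_outcome)` for the two scene pools, or, in
#'   `"stay-vs-all"` mode, `c(stay, all_non_stay)`.
#' @return List with `p_fisher` (two-sided), `phi`
#'   (`(ad - bc) / sqrt((a+b)(c+d)(a+c)(b+d))`), `odds_ratio` and its 95%
#'   CI, and the 2 x 2 `table`.
#' @export
stay_proportion_test <- function(counts_nonswitch, counts_switch) {
  tab <- rbind(nonswitch = counts_nonswitch, switch = counts_switch)
  if (any(tab < 0) || any(tab != round(tab))) {
    stop("counts must be nonnegative integers")
  }
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  margins <- c(a + b, c + d, a + c, b + d)
  if (any(margins == 0)) stop("phi is undefined for a zero margin")
  ft <- fisher.test(tab)
  phi <- unname((a * d - b * c) / sqrt(prod(margins)))
  list(p_fisher = ft$p.value, phi = phi,
       odds_ratio = unname(ft$estimate), or_ci = unname(ft$conf.int),
       table = tab)
}

#' Build the stay 2 x 2 table from an action-count table
#'
#' @param counts Per-scene action counts for one monkey (columns `scene`,
#'   `Return`, `Stay`, ...).
#' @param mode `"stay-vs-return"` (primary) or `"stay-vs-all"`.
#' @return 2 x 2 integer matrix (rows: non-switch, switch).
#' @export
stay_table <- function(counts, mode = c("stay-vs-return", "stay-vs-all")) {
  mode <- match.arg(mode)
  pool <- function(scenes) {
    sub <- counts[counts$scene %in% scenes, ]
    stay <- sum(sub$Stay)
    other <- if (mode == "stay-vs-return") sum(sub$Return) else
      sum(sub$total) - stay
    c(stay = stay, other = other)
  }
  rbind(nonswitch = pool(c(1, 2)), switch = pool(c(3, 4)))
}
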