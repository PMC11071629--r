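#' Event-aligned PSTH in 1-ms bins
#'
#' Bins spike times relative to each event into half-open 1-ms bins
#' `[event + b, event + b + 1)`. A spike exactly at the event time falls in
#' bin `[0, 1)`.
#'
#' @param spikes Sorted numeric vector of spike times, ms.
#' @param event_times Numeric vector of alignment events, ms.
#' @param window Length-2 `c(pre, post)` window relative to the event, ms
#'   (`pre < post`); bins cover `[pre, post)`.
#' @return An `aligned_psth`: list with `counts` (trials x bins integer
#'   matrix), `bins` (left edges, ms), and `window`.
#' @export
align_and_bin <- function(spikes, event_times, window = c(-500, 500)) {
  if (length(event_times) == 0L) stop("event_times must be non-empty")
  if (window[1] >= window[2]) stop("window must satisfy pre < post")
  bins <- seq(window[1], window[2] - 1)
  nb <- length(bins)
  counts <- matrix(0L, nrow = length(event_times), ncol = nb)
  for (i in seq_along(event_times)) {
    rel <- spikes - event_times[i]
    rel <- rel[rel >= window[1] & rel < window[2]]
    if (length(rel)) {
      idx <- floor(rel - window[1]) + 1L
      counts[i, ] <- tabulate(idx, nbins = nb)
    }
  }
  structure(list(counts = counts, bins = bins, window = window),
            class = "aligned_psth")
}

gaussian_kernel <- function(sigma, dt = 1) {
  half <- ceiling(4 * sigma / dt)
  k <- dnorm(seq(-half, half) * dt, sd = sigma)
  k / sum(k)                       # renormalize after +/-4 sigma truncation
}

#' Gaussian spike-density function from a PSTH
#'
#' Convolves the trial-averaged 1-ms PSTH with a unit-area Gaussian kernel
#' (sigma in ms, truncated at +/-4 sigma and renormalized) and scales to
#' spikes/s. Zero padding at the edges; total area is conserved to within
#' the truncated kernel mass.
#'
#' @param psth An `aligned_psth`.
#' @param sigma Kernel SD, ms.
#' @return Numeric rate trace (spikes/s), one value per bin, with the bin
#'   grid attached as attribute `bins`.
#' @export
smooth_sdf <- function(psth, sigma = 20) {
  if (sigma <= 0) stop("sigma must be positive")
  avg <- colMeans(psth$counts)          # spikes per 1-ms bin per trial
  k <- gaussian_kernel(sigma)
  half <- (length(k) - 1) / 2
  padded <- c(rep(0, half), avg, rep(0, half))
  sm <- vapply(seq_along(avg), function(i) {
    sum(padded[i:(i + 2 * half)] * rev(k))
  }, numeric(1))
  structure(sm * 1000, bins = psth$bins)
}

#' Baseline firing statistics
#'
#' Per-trial mean firing rates in a fixed pre-event window, summarized as
#' an across-trial mean and SD. Two windows are used in the analysis:
#' `pre_event_500` (500 ms immediately before the aligning event, used for
#' Z-normalization) and `pre_scene_1000` (1500 to 500 ms before scene
#' onset, used for the neuron inclusion filter).
#'
#' @param spikes Spike times, ms.
#' @param event_times Aligning events, ms.
#' @param mode `"pre_event_500"` or `"pre_scene_1000"`.
#' @return List with `mean`, `sd` (spikes/s), `per_trial` rates, and
#'   `degenerate` (`TRUE` when the SD is zero, e.g. no spikes).
#' @export
baseline_stats <- function(spikes, event_times,
                           mode = c("pre_event_500", "pre_scene_1000")) {
  mode <- match.arg(mode)
  window <- if (mode == "pre_event_500") c(-500, 0) else c(-1500, -500)
  dur_s <- diff(window) / 1000
  per_trial <- vapply(event_times, function(ev) {
    sum(spikes >= ev + window[1] & spikes < ev + window[2]) / dur_s
  }, numeric(1))
  s <- if (length(per_trial) > 1) sd(per_trial) else 0
  list(mean = mean(per_trial), sd = s, per_trial = per_trial,
       degenerate = s == 0)
}

#' Z-score a rate trace against its baseline
#'
#' Subtracts the baseline mean and divides by the baseline SD. Degenerate
#' baselines (SD = 0) raise an error unless `allow_degenerate = TRUE`, in
#' which case `NA`s are returned and the result is flagged; such neurons
#' are excluded from population maps rather than epsilon-padded.
#'
#' @param sdf Rate trace (spikes/s), e.g. from [smooth_sdf()].
#' @param baseline List with `mean` and `sd`, from [baseline_stats()].
#' @param allow_degenerate Return flagged `NA`s instead of erroring when
#'   the baseline SD is zero.
#' @return A `normalized_sdf`: list with `rate_z`, `baseline_mean`,
#'   `baseline_sd`, `degenerate`.
#' @export
zscore_sdf <- function(sdf, baseline, allow_degenerate = FALSE) {
  if (baseline$sd <= 0) {
    if (!allow_degenerate) {
      stop("baseline SD is zero; neuron flagged degenerate")
    }
    return(structure(list(rate_z = rep(NA_real_, length(sdf)),
                          baseline_mean = baseline$mean, baseline_sd = 0,
                          degenerate = TRUE), class = "normalized_sdf"))
  }
  structure(list(rate_z = (as.numeric(sdf) - baseline$mean) / baseline$sd,
                 baseline_mean = baseline$mean, baseline_sd = baseline$sd,
                 degenerate = FALSE, bins = attr(sdf, "bins")),
            class = "normalized_sdf")
}

#' Mean of a trace over a half-open window
#'
#' @param trace Numeric trace on a 1-ms bin grid; the grid is taken from
#'   the `bins` attribute unless given explicitly.
#' @param window Length-2 `c(start, end)`, ms, half-open `[start, end)`.
#' @param bins Optional explicit bin grid (left edges, ms).
#' @return Arithmetic mean of the trace over the window.
#' @export
window_mean <- function(trace, window, bins = NULL) {
  if (is.null(bins)) bins <- attr(trace, "bins")
  if (is.list(trace) && !is.null(trace$rate_z)) {
    if (is.null(bins)) bins <- trace$bins
    trace <- trace$rate_z
  }
  if (is.null(bins)) stop("trace has no bin grid")
  sel <- bins >= window[1] & bins < window[2]
  if (!any(sel)) stop("window does not overlap the trace")
  mean(trace[sel])
}

#' Baseline-rate inclusion filter
#'
#' Neurons are included only when their baseline firing rate, measured
#' 1500 to 500 ms before scene onset, is strictly below `max_rate`
#' spikes/s -- the operational criterion for putative medium spiny neurons
#' (higher-rate units are treated as fast-spiking interneurons).
#'
#' @param session An `ephys_session`.
#' @param max_rate Exclusion threshold, spikes/s.
#' @return `TRUE` if the neuron passes the filter.
#' @export
inclusion_filter <- function(session, max_rate = 10) {
  ev <- session$trials$t_scene_ms
  ev <- ev[!is.na(ev)]
  if (length(ev) < 10) stop("need at least 10 scene events")
  b <- baseline_stats(session$spikes, ev, mode = "pre_scene_1000")
  b$mean < max_rate
}

#' Per-trial Z-scored window activity
#'
#' The workhorse behind activity tables and cluster features: for each
#' event, the mean firing rate in `window` (half-open, ms relative to the
#' event) minus the baseline mean, divided by the baseline SD. The
#' baseline is the across-trial distribution of 500-ms pre-event mean
#' rates over `baseline_events` (defaulting to the aligning events).
#'
#' @param spikes Spike times, ms.
#' @param event_times Aligning events, ms.
#' @param window Analysis window, ms relative to the event.
#' @param baseline_events Events defining the baseline window population.
#' @return List with `z` (per-trial Z values), `rate` (per-trial raw
#'   rates, spikes/s), and `baseline`.
#' @export
trial_window_activity <- function(spikes, event_times, window = c(100, 300),
                                  baseline_events = event_times) {
  base <- baseline_stats(spikes, baseline_events, mode = "pre_event_500")
  dur_s <- diff(window) / 1000
  rate <- vapply(event_times, function(ev) {
    sum(spikes >= ev + window[1] & spikes < ev + window[2]) / dur_s
  }, numeric(1))
  z <- if (base$sd > 0) (rate - base$mean) / base$sd else
    rep(NA_real_, length(rate))
  list(z = z, rate = rate, baseline = base)
}

#' Population SDF for one condition of one session
#'
#' Event-aligned, Gaussian-smoothed, baseline-Z-scored firing rate trace.
#'
#' @param session An `ephys_session`.
#' @param event_times Aligning events, ms.
#' @param window PSTH window `c(pre, post)`, ms.
#' @param sigma Smoothing SD, ms.
#' @param allow_degenerate Passed to [zscore_sdf()].
#' @return A `normalized_sdf`.
#' @export
session_sdf <- function(session, event_times, window = c(-500, 600),
                        sigma = 20, allow_degenerate = TRUE) {
  psth <- align_and_bin(session$spikes, event_times, window)
  sdf <- smooth_sdf(psth, sigma = sigma)
  base <- baseline_stats(session$spikes, event_times,
                         mode = "pre_event_500")
  zscore_sdf(sdf, base, allow_degenerate = allow_degenerate)
}

epoch_events <- function(session, epoch) {
  tr <- session$trials
  switch(epoch,
    scene_onset = list(times = tr$t_scene_ms,
                       labels = data.frame(Scene = tr$scene)),
    target_onset = {
      keep <- !is.na(tr$t_target_ms)
      list(times = tr$t_target_ms[keep],
           labels = data.frame(Scene = tr$scene[keep],
                               Value = tr$value[keep],
                               Direction = tr$direction[keep]))
    },
    saccade_onset = {
      keep <- !is.na(tr$t_saccade_go_ms) &
        tr$action %in% c("Accept", "Return")
      list(times = tr$t_saccade_go_ms[keep],
           labels = data.frame(Value = tr$value[keep],
                               Direction = tr$direction[keep]))
    },
    saccade_back = {
      keep <- !is.na(tr$t_saccade_back_ms)
      list(times = tr$t_saccade_back_ms[keep],
           labels = data.frame(Value = tr$value[keep],
                               Direction = tr$direction[keep]))
    },
    fixation_object = {
      obj <- session$objects
      if (is.null(obj)) stop("session has no object table")
      list(times = obj$t_object_ms,
           labels = data.frame(Value = obj$value,
                               Direction = obj$direction))
    },
    stop("unknown epoch: ", epoch))
}

#' Long-format activity table for a set of sessions
#'
#' For each session (neuron) and condition cell of the chosen epoch,
#' computes the cell-mean Z-scored window activity. One row per neuron x
#' cell -- the input format of the mixed-model stage.
#'
#' @param sessions List of `ephys_session`s.
#' @param epoch One of `"scene_onset"`, `"target_onset"`,
#'   `"saccade_onset"`, `"saccade_back"`, `"fixation_object"`.
#' @param window Analysis window, ms relative to the epoch event.
#' @param min_trials Cells with fewer trials are dropped (with a message).
#' @return Data frame with `NeuronalActivity`, condition factors,
#'   `monkey_ID`, `Neuron_ID`, `epoch`, `n_trials`.
#' @export
activity_table <- function(sessions, epoch = "target_onset",
                           window = NULL, min_trials = 1) {
  if (is.null(window)) {
    window <- analysis_windows()[[sub("_onset|_object|_back", "", epoch)]]
    if (is.null(window)) window <- c(100, 300)
  }
  rows <- list()
  for (s in sessions) {
    ev <- epoch_events(s, epoch)
    if (length(ev$times) == 0L) next
    act <- trial_window_activity(s$spikes, ev$times, window = window)
    if (act$baseline$degenerate) {
      message("neuron ", s$neuron_id, ": degenerate baseline, skipped")
      next
    }
    cells <- ev$labels
    key <- interaction(cells, drop = TRUE)
    for (lev in levels(key)) {
      sel <- key == lev
      if (sum(sel) < min_trials) {
        message("neuron ", s$neuron_id, ": cell ", lev, " has ",
                sum(sel), " trials, dropped")
        next
      }
      row <- cells[which(sel)[1], , drop = FALSE]
      row$NeuronalActivity <- mean(act$z[sel])
      row$monkey_ID <- s$monkey_id
      row$Neuron_ID <- paste(s$monkey_id, s$neuron_id, sep = "_")
      row$epoch <- epoch
      row$n_trials <- sum(sel)
      rows[[length(rows) + 1L]] <- row
    }
  }
  if (length(rows) == 0L) stop("no activity rows produced")
  out <- do.call(rbind, rows)
  for (col in intersect(c("Scene", "Value", "Direction"), names(out))) {
    out[[col]] <- factor(out[[col]])
  }
  out$monkey_ID <- factor(out$monkey_ID)
  out$Neuron_ID <- factor(out$Neuron_ID)
  rownames(out) <- NULL
  out
}
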