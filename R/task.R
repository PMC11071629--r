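#' Task geometry and timing configuration
#'
#' Defines the spatial and temporal layout of the choice and fixation tasks:
#' target eccentricity and the six possible target angles, the hold duration
#' that turns a target fixation into an acceptance, fixation-point timing,
#' and the object presentation schedule of the fixation task. Defaults follow
#' the task design the synthetic generator emulates.
#'
#' All target angles must have a nonzero horizontal component so that every
#' target is unambiguously contralateral or ipsilateral to the recorded
#' hemisphere.
#'
#' @param n_scenes Number of scene (background) conditions.
#' @param target_eccentricity_deg Target eccentricity, degrees of visual angle.
#' @param target_angles_deg Possible target angles, degrees (0 = right).
#' @param accept_hold_ms Minimum target fixation that counts as acceptance.
#' @param fp_hold_ms Required central fixation before target onset.
#' @param scene_free_view_ms Free-viewing period between scene onset and
#'   fixation-point onset.
#' @param prep_interval_ms Length-2 range of the preparatory interval before
#'   scene onset; each trial draws uniformly from it.
#' @param fixation_object_ms Object presentation duration in the fixation task.
#' @param fixation_isi_ms Interstimulus interval in the fixation task.
#' @param reward_delay_fixation_ms Delay from last object to reward in the
#'   fixation task.
#' @param eye_rate_hz Eye-tracker sampling rate. The analysis assumes 1000 Hz.
#' @param target_halfwidth_deg Half-width of the square target acceptance
#'   window (the full window is `2 * target_halfwidth_deg` per side).
#' @return An object of class `task_config`.
#' @export
task_config <- function(n_scenes = 4L,
                        target_eccentricity_deg = 15,
                        target_angles_deg = c(0, 45, 135, 180, 225, 315),
                        accept_hold_ms = 400,
                        fp_hold_ms = 700,
                        scene_free_view_ms = 1000,
                        prep_interval_ms = c(1500, 2000),
                        fixation_object_ms = 400,
                        fixation_isi_ms = 400,
                        reward_delay_fixation_ms = 300,
                        eye_rate_hz = 1000,
                        target_halfwidth_deg = 4) {
  cfg <- list(
    n_scenes = as.integer(n_scenes),
    target_eccentricity_deg = target_eccentricity_deg,
    target_angles_deg = target_angles_deg,
    accept_hold_ms = accept_hold_ms,
    fp_hold_ms = fp_hold_ms,
    scene_free_view_ms = scene_free_view_ms,
    prep_interval_ms = prep_interval_ms,
    fixation_object_ms = fixation_object_ms,
    fixation_isi_ms = fixation_isi_ms,
    reward_delay_fixation_ms = reward_delay_fixation_ms,
    eye_rate_hz = eye_rate_hz,
    target_halfwidth_deg = target_halfwidth_deg
  )
  durations <- c(cfg$accept_hold_ms, cfg$fp_hold_ms, cfg$scene_free_view_ms,
                 cfg$prep_interval_ms, cfg$fixation_object_ms,
                 cfg$fixation_isi_ms, cfg$reward_delay_fixation_ms)
  if (any(durations <= 0)) stop("all task durations must be positive")
  if (length(cfg$prep_interval_ms) != 2L ||
      diff(cfg$prep_interval_ms) < 0) {
    stop("prep_interval_ms must be an increasing length-2 range")
  }
  if (any(abs(cos(cfg$target_angles_deg * pi / 180)) < 1e-9)) {
    stop("target angles must have a nonzero horizontal component")
  }
  if (cfg$target_eccentricity_deg <= cfg$target_halfwidth_deg) {
    stop("target eccentricity must exceed the target half-width")
  }
  class(cfg) <- "task_config"
  cfg
}

#' Printed action-count table for bad objects
#'
#' Per-monkey, per-scene counts of the five possible responses to bad-object
#' presentations (Accept, Return, Stay, Other, fixation break), as printed in
#' the study's behavioral summary. These counts parameterize the default
#' behavioral policy of the synthetic generator, and the behavioral summary
#' stage reproduces the published percentages from them.
#'
#' @param pooled If `TRUE`, append the pooled non-switch (scenes 1-2) and
#'   switch (scenes 3-4) rows.
#' @return A data frame with columns `monkey`, `scene`, `total`, `Accept`,
#'   `Return`, `Stay`, `Other`, `FixBreak`.
#' @export
action_count_table <- function(pooled = FALSE) {
  path <- system.file("extdata", "table_action_counts.tsv",
                      package = "choicephys", mustWork = TRUE)
  tbl <- read.delim(path, stringsAsFactors = FALSE)
  if (pooled) {
    pool <- function(scenes, label) {
      sub <- tbl[tbl$scene %in% scenes, ]
      agg <- aggregate(sub[, c("total", "Accept", "Return", "Stay",
                               "Other", "FixBreak")],
                       by = list(monkey = sub$monkey), FUN = sum)
      agg$scene <- label
      agg[, names(tbl)]
    }
    tbl$scene <- as.character(tbl$scene)
    tbl <- rbind(tbl, pool(c(1, 2), "nonswitch"), pool(c(3, 4), "switch"))
  }
  tbl
}

#' Printed saccade reaction-time summary table
#'
#' Per-monkey, per-scene, per-value sample sizes, means, SDs and 95% CIs of
#' saccade reaction times (good objects: accept saccades; bad objects:
#' return-go saccades only). These values parameterize the reaction-time
#' component of the default behavioral policy.
#'
#' @return A data frame with columns `monkey`, `scene`, `value`, `n`,
#'   `mean_rt_ms`, `sd_ms`, `ci_lo`, `ci_hi`.
#' @export
rt_summary_table <- function() {
  path <- system.file("extdata", "table_saccade_rt.tsv",
                      package = "choicephys", mustWork = TRUE)
  read.delim(path, stringsAsFactors = FALSE)
}

#' Behavioral policy for the synthetic generator
#'
#' A behavioral policy specifies, per scene and object value, the reaction
#' time distribution (truncated normal) and the probabilities of the five
#' possible actions. The default policy is derived from the printed
#' behavioral tables: reaction-time means/SDs from the reaction-time summary
#' and bad-object action probabilities from the action-count table; good
#' objects are always accepted.
#'
#' @param monkey Monkey label, `"C"` or `"S"`, selecting the printed table.
#' @param rt_bounds_ms Truncation bounds for sampled reaction times.
#' @return An object of class `behavior_policy`: a data frame with one row
#'   per (scene, value) and columns `rt_mean`, `rt_sd`, and action
#'   probabilities `p_Accept`, `p_Return`, `p_Stay`, `p_Other`, `p_FixBreak`.
#' @export
behavior_policy <- function(monkey = "C", rt_bounds_ms = c(80, 600)) {
  monkey <- match.arg(monkey, c("C", "S"))
  rt <- rt_summary_table()
  ac <- action_count_table()
  rt <- rt[rt$monkey == monkey, ]
  ac <- ac[ac$monkey == monkey, ]
  rows <- expand.grid(scene = 1:4, value = c("good", "bad"),
                      stringsAsFactors = FALSE)
  pol <- lapply(seq_len(nrow(rows)), function(i) {
    sc <- rows$scene[i]; val <- rows$value[i]
    r <- rt[rt$scene == sc & rt$value == val, ]
    if (val == "good") {
      p <- c(Accept = 1, Return = 0, Stay = 0, Other = 0, FixBreak = 0)
    } else {
      a <- ac[ac$scene == sc, ]
      p <- c(Accept = a$Accept, Return = a$Return, Stay = a$Stay,
             Other = a$Other, FixBreak = a$FixBreak) / a$total
    }
    data.frame(scene = sc, value = val, rt_mean = r$mean_rt_ms,
               rt_sd = r$sd_ms, p_Accept = p[["Accept"]],
               p_Return = p[["Return"]], p_Stay = p[["Stay"]],
               p_Other = p[["Other"]], p_FixBreak = p[["FixBreak"]])
  })
  pol <- do.call(rbind, pol)
  attr(pol, "monkey") <- monkey
  attr(pol, "rt_bounds_ms") <- rt_bounds_ms
  class(pol) <- c("behavior_policy", "data.frame")
  validate_policy(pol)
  pol
}

validate_policy <- function(policy) {
  pcols <- c("p_Accept", "p_Return", "p_Stay", "p_Other", "p_FixBreak")
  if (!all(pcols %in% names(policy))) {
    stop("policy is missing action probability columns")
  }
  pm <- as.matrix(policy[, pcols])
  if (any(pm < 0)) stop("action probabilities must be nonnegative")
  if (any(abs(rowSums(pm) - 1) > 1e-9)) {
    stop("action probabilities must sum to 1 within 1e-9")
  }
  if (any(policy$rt_sd <= 0)) stop("rt_sd must be positive")
  good <- policy[policy$value == "good", ]
  bad <- policy[policy$value == "bad", ]
  if (any(good$rt_mean[order(good$scene)] >= bad$rt_mean[order(bad$scene)])) {
    stop("good-object mean RT must be below bad-object mean RT per scene")
  }
  invisible(policy)
}

#' Neuronal response archetypes
#'
#' Parametric descriptions of the three response types used by the spike
#' generator. Each archetype has a baseline rate (< 10 spikes/s, the
#' inclusion criterion for putative medium spiny neurons), a
#' difference-of-exponentials transient response kernel whose amplitude
#' depends on object value and direction, an attenuation multiplier applied
#' during the fixation task, and an optional signed gain coupling trial
#' reaction time to response amplitude.
#'
#' The three defaults encode the qualitative taxonomy the analysis is built
#' to recover:
#' * `cluster1_good`: good-preferring, contralateral bias, negative
#'   latency coupling for contralateral good objects (stronger response on
#'   short-latency trials);
#' * `cluster2_bad`: bad-preferring (rejection-related), direction-neutral;
#' * `cluster3_visual`: value-agnostic early transient, with an additional
#'   sustained component for bad objects.
#'
#' @param label One of `"cluster1_good"`, `"cluster2_bad"`,
#'   `"cluster3_visual"`.
#' @param baseline_rate Baseline firing rate, spikes/s, in (0, 10).
#' @param latency_ms,rise_ms,decay_ms Kernel latency and time constants.
#' @param amplitude 2 x 2 matrix of peak response amplitudes (spikes/s),
#'   rows `good`/`bad`, columns `contra`/`ipsi`.
#' @param sustain_amplitude Named numeric (`good`, `bad`): amplitude of an
#'   additional slow-decay component (decay `sustain_decay_ms`).
#' @param sustain_decay_ms Decay constant of the sustained component.
#' @param fixation_attenuation Multiplier in `[0, 1]` applied to response
#'   amplitudes during the fixation task.
#' @param latency_coupling Signed gain linking standardized trial RT to
#'   response amplitude; applied only to the conditions named in
#'   `coupling_conditions`.
#' @param coupling_conditions Character vector of `"value.direction"` cells
#'   the latency coupling applies to.
#' @param gain_sd SD of the per-neuron log-normal response gain, capturing
#'   across-neuron amplitude heterogeneity within an archetype.
#' @return An object of class `neuron_archetype`.
#' @export
neuron_archetype <- function(label = c("cluster1_good", "cluster2_bad",
                                       "cluster3_visual"),
                             baseline_rate = 5,
                             latency_ms = 90, rise_ms = 20, decay_ms = 80,
                             amplitude = NULL,
                             sustain_amplitude = c(good = 0, bad = 0),
                             sustain_decay_ms = 300,
                             fixation_attenuation = 0.3,
                             latency_coupling = 0,
                             coupling_conditions = character(0),
                             gain_sd = 0.1) {
  label <- match.arg(label)
  if (is.null(amplitude)) {
    amplitude <- switch(label,
      cluster1_good = matrix(c(35, 20, 7, 6), 2, 2, byrow = TRUE,
                             dimnames = list(c("good", "bad"),
                                             c("contra", "ipsi"))),
      cluster2_bad = matrix(c(7, 7, 33, 32), 2, 2, byrow = TRUE,
                            dimnames = list(c("good", "bad"),
                                            c("contra", "ipsi"))),
      cluster3_visual = matrix(c(30, 28, 30, 28), 2, 2, byrow = TRUE,
                               dimnames = list(c("good", "bad"),
                                               c("contra", "ipsi"))))
    if (label == "cluster3_visual") {
      sustain_amplitude <- c(good = 0, bad = 5)
    }
    if (label == "cluster1_good" && identical(latency_coupling, 0) &&
        length(coupling_conditions) == 0L) {
      latency_coupling <- -0.5
      coupling_conditions <- "good.contra"
    }
  }
  arch <- list(label = label, baseline_rate = baseline_rate,
               latency_ms = latency_ms, rise_ms = rise_ms,
               decay_ms = decay_ms, amplitude = amplitude,
               sustain_amplitude = sustain_amplitude,
               sustain_decay_ms = sustain_decay_ms,
               fixation_attenuation = fixation_attenuation,
               latency_coupling = latency_coupling,
               coupling_conditions = coupling_conditions,
               gain_sd = gain_sd)
  validate_archetype(arch)
  class(arch) <- "neuron_archetype"
  arch
}

validate_archetype <- function(arch) {
  if (!(arch$baseline_rate > 0 && arch$baseline_rate < 10)) {
    stop("baseline_rate must lie in (0, 10) spikes/s")
  }
  a <- arch$amplitude
  if (!identical(dim(a), c(2L, 2L))) stop("amplitude must be a 2 x 2 matrix")
  if (any(a < 0)) stop("amplitudes must be nonnegative")
  if (arch$fixation_attenuation < 0 || arch$fixation_attenuation > 1) {
    stop("fixation_attenuation must lie in [0, 1]")
  }
  if (arch$label == "cluster1_good" &&
      !(a["good", "contra"] > a["bad", "contra"] &&
        a["good", "contra"] > a["good", "ipsi"])) {
    stop("cluster1_good requires good > bad and contra > ipsi amplitudes")
  }
  if (arch$label == "cluster2_bad" &&
      !(a["bad", "contra"] > a["good", "contra"] &&
        abs(a["bad", "contra"] - a["bad", "ipsi"]) <=
          0.2 * max(a["bad", ]))) {
    stop("cluster2_bad requires bad > good and contra ~ ipsi amplitudes")
  }
  invisible(arch)
}

#' Default archetype population mix
#'
#' The number of neurons per archetype used by the full pipeline, matching
#' the cluster sizes the analysis is expected to recover.
#'
#' @return Named integer vector.
#' @export
default_population <- function() {
  c(cluster1_good = 38L, cluster2_bad = 47L, cluster3_visual = 53L)
}

#' Named analysis-window presets
#'
#' The epoch windows used throughout the analysis, ms relative to the
#' aligning event. `scene`, `target` and `saccade` are the primary 100-300 ms
#' post-event windows; `saccade_peri` (200 ms from 150 ms before saccade
#' initiation) and `target_early` (150 ms from 50 ms after target onset) are
#' alternative presets for the saccade-aligned and latency analyses.
#'
#' @return Named list of length-2 numeric windows `c(start, end)`, half-open.
#' @export
analysis_windows <- function() {
  list(scene = c(100, 300), target = c(100, 300), saccade = c(100, 300),
       object = c(100, 300), saccade_peri = c(-150, 50),
       target_early = c(50, 200))
}
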