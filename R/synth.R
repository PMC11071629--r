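#' @section Eye-movement synthesis:
#' Saccades are generated as minimum-jerk displacements with duration
#' `20 ms + 1.5 ms/deg` of amplitude. The movement is time-shifted so that
#' the first 1-ms central-difference speed sample exceeding the 40 deg/s
#' detection threshold falls on the commanded onset time; commanded onsets
#' and detected onsets therefore agree on noiseless traces.
#' @name synth-internal
#' @keywords internal
NULL

# Minimum-jerk position profile s(tau), tau in [0, 1].
minjerk_s <- function(tau) 10 * tau^3 - 15 * tau^4 + 6 * tau^5

saccade_duration_ms <- function(amplitude_deg) 20 + 1.5 * amplitude_deg

# Offset (ms) from kinematic movement start to the first 1-ms
# central-difference sample whose speed exceeds `threshold` deg/s.
saccade_threshold_lag <- function(amplitude_deg, threshold = 40) {
  if (amplitude_deg <= 0) return(0)
  dur <- saccade_duration_ms(amplitude_deg)
  t <- seq(0, ceiling(dur) + 2)
  pos <- amplitude_deg * minjerk_s(pmin(pmax(t / dur, 0), 1))
  n <- length(pos)
  speed <- c(0, (pos[3:n] - pos[1:(n - 2)]) / 2, 0) * 1000
  idx <- which(speed > threshold)
  if (length(idx) == 0L) {
    stop("saccade of ", amplitude_deg, " deg never exceeds ", threshold,
         " deg/s; amplitude too small for detection")
  }
  t[idx[1]]
}

# Slow fixational jitter: white noise low-passed with a Gaussian kernel
# (sigma_ms) and rescaled to the requested position SD, so that position
# noise does not alias into saccade-band velocities.
fixational_noise <- function(n, sd_deg, sigma_ms = 25) {
  half <- 4 * sigma_ms
  k <- dnorm(seq(-half, half), sd = sigma_ms)
  k <- k / sqrt(sum(k^2))      # unit output variance before scaling
  w <- rnorm(n + 2 * half)
  sm <- stats::filter(w, k, method = "convolution", sides = 2)
  as.numeric(sm[(half + 1):(half + n)]) * sd_deg
}

#' Build an eye-position trace from saccade commands
#'
#' Low-level constructor used by [synthesize_eye_trace()]. Between commands
#' the gaze holds its current position (plus isotropic Gaussian jitter);
#' each command produces a minimum-jerk displacement whose detectable onset
#' (first 1-ms central-difference speed sample above 40 deg/s) coincides
#' with the commanded onset time.
#'
#' @param commands Data frame with columns `t_ms` (commanded onset), `x_deg`,
#'   `y_deg` (landing point). Commands must be time-ordered and
#'   non-overlapping.
#' @param duration_ms Total trace duration; samples run `0 .. duration_ms`.
#' @param noise_sd Gaussian position noise SD, degrees, added per sample.
#' @param start Length-2 starting gaze position, degrees.
#' @return An `eye_trace`: data frame with `t_ms`, `x_deg`, `y_deg` on a
#'   uniform 1-ms grid.
#' @export
eye_trace_from_commands <- function(commands, duration_ms, noise_sd = 0,
                                    start = c(0, 0)) {
  t <- 0:ceiling(duration_ms)
  x <- rep(start[1], length(t))
  y <- rep(start[2], length(t))
  if (!is.null(commands) && nrow(commands) > 0) {
    commands <- commands[order(commands$t_ms), , drop = FALSE]
    # resolve no-op commands and movement geometry first
    pos <- start
    eff <- list()
    for (i in seq_len(nrow(commands))) {
      x1 <- commands$x_deg[i]; y1 <- commands$y_deg[i]
      amp <- sqrt((x1 - pos[1])^2 + (y1 - pos[2])^2)
      if (amp < 1e-12) next
      eff[[length(eff) + 1L]] <-
        list(t_ms = commands$t_ms[i], from = pos, to = c(x1, y1),
             dur = saccade_duration_ms(amp),
             lag = saccade_threshold_lag(amp))
      pos <- c(x1, y1)
    }
    n_t <- length(t)
    last_end <- -Inf
    for (i in seq_along(eff)) {
      e <- eff[[i]]
      t_start <- e$t_ms - e$lag
      if (t_start < last_end) {
        stop("overlapping saccade commands at t = ", e$t_ms, " ms")
      }
      # fill the movement profile, then hold the landing point until the
      # next command takes over
      i0 <- max(1L, floor(t_start) + 1L)
      i_next <- if (i < length(eff)) {
        min(n_t, floor(eff[[i + 1]]$t_ms) + 1L)
      } else n_t
      if (i0 <= i_next) {
        idx <- i0:i_next
        s <- minjerk_s(pmin(pmax((t[idx] - t_start) / e$dur, 0), 1))
        x[idx] <- e$from[1] + (e$to[1] - e$from[1]) * s
        y[idx] <- e$from[2] + (e$to[2] - e$from[2]) * s
      }
      last_end <- t_start + e$dur
    }
  }
  if (noise_sd > 0) {
    x <- x + fixational_noise(length(t), noise_sd)
    y <- y + fixational_noise(length(t), noise_sd)
  }
  trace <- data.frame(t_ms = t, x_deg = x, y_deg = y)
  class(trace) <- c("eye_trace", "data.frame")
  trace
}

target_position <- function(angle_deg, eccentricity_deg) {
  c(eccentricity_deg * cos(angle_deg * pi / 180),
    eccentricity_deg * sin(angle_deg * pi / 180))
}

is_contra <- function(angle_deg, hemisphere) {
  x <- cos(angle_deg * pi / 180)
  (hemisphere == "left" & x > 0) | (hemisphere == "right" & x < 0)
}

# Derive the deterministic saccade command list implied by a trial table.
saccade_commands <- function(trials, task) {
  ecc <- task$target_eccentricity_deg
  cmds <- list()
  add <- function(t, xy) {
    cmds[[length(cmds) + 1L]] <<- data.frame(t_ms = t, x_deg = xy[1],
                                             y_deg = xy[2])
  }
  for (i in seq_len(nrow(trials))) {
    tr <- trials[i, ]
    tgt <- target_position(tr$angle_deg, ecc)
    go <- tr$t_saccade_go_ms
    if (tr$action == "FixBreak") {
      # break saccade upward out of the fixation zone, then re-center
      add(go, c(0, 8))
      add(go + 500, c(0, 0))
    } else if (tr$action == "Accept") {
      add(go, tgt)
      # re-center after the reward
      add(go + saccade_duration_ms(ecc) + task$accept_hold_ms + 150, c(0, 0))
    } else if (tr$action == "Return") {
      add(go, tgt)
      add(tr$t_saccade_back_ms, c(0, 0))
    } else if (tr$action == "Other") {
      add(go, target_position(tr$angle_deg + 90, ecc))
      add(tr$t_target_ms + 1100, c(0, 0))
    }
  }
  if (length(cmds) == 0L) {
    return(data.frame(t_ms = numeric(0), x_deg = numeric(0),
                      y_deg = numeric(0)))
  }
  do.call(rbind, cmds)
}

#' Synthesize a session eye trace from a trial table
#'
#' Reconstructs the gaze trajectory implied by the trial records: fixation
#' at the center, accept/return/other/fix-break saccades at their commanded
#' times, and deterministic re-centering movements. Commanded saccade onsets
#' are recoverable by [detect_saccade()] to within +/-2 ms on noiseless
#' traces.
#'
#' @param trials Trial table as produced by [simulate_choice_session()].
#' @param task A [task_config()].
#' @param noise_sd Gaussian position noise SD, degrees.
#' @param seed Optional integer seed for the noise draw.
#' @return An `eye_trace` covering `0 .. max(event) + 1000` ms.
#' @export
synthesize_eye_trace <- function(trials, task, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.unsorted(trials$t_scene_ms)) stop("trials must be time-ordered")
  cmds <- saccade_commands(trials, task)
  t_end <- max(trials$t_end_ms, na.rm = TRUE) + 1000
  eye_trace_from_commands(cmds, t_end, noise_sd = noise_sd)
}

# Difference-of-exponentials kernel, peak-normalized to 1.
response_kernel <- function(t_rel, latency, rise, decay) {
  k <- numeric(length(t_rel))
  tt <- t_rel - latency
  on <- tt >= 0
  if (abs(decay - rise) < 1e-9) {
    k[on] <- (tt[on] / rise) * exp(1 - tt[on] / rise)
  } else {
    tpk <- rise * decay / (decay - rise) * log(decay / rise)
    peak <- exp(-tpk / decay) - exp(-tpk / rise)
    k[on] <- (exp(-tt[on] / decay) - exp(-tt[on] / rise)) / peak
  }
  k
}

# Assemble the 1-kHz firing-rate profile (spikes/s) implied by a trial or
# object event table. `events` needs columns t_ms, value, direction and
# optionally gain (amplitude multiplier per event).
session_rate_profile <- function(events, archetype, t_end_ms,
                                 attenuation = 1) {
  n <- ceiling(t_end_ms)
  rate <- rep(archetype$baseline_rate, n)
  if (nrow(events) > 0) {
    span_tr <- ceiling(archetype$latency_ms + 8 * archetype$decay_ms)
    ktr <- response_kernel(seq_len(span_tr) - 1, archetype$latency_ms,
                           archetype$rise_ms, archetype$decay_ms)
    span_su <- ceiling(archetype$latency_ms + 6 * archetype$sustain_decay_ms)
    ksu <- response_kernel(seq_len(span_su) - 1, archetype$latency_ms,
                           archetype$rise_ms, archetype$sustain_decay_ms)
    gain <- if ("gain" %in% names(events)) events$gain else rep(1, nrow(events))
    for (i in seq_len(nrow(events))) {
      ev <- events[i, ]
      amp <- archetype$amplitude[ev$value, ev$direction] * gain[i] *
        attenuation
      sus <- archetype$sustain_amplitude[[ev$value]] * attenuation
      i0 <- floor(ev$t_ms) + 1L
      if (amp != 0) {
        idx <- i0:min(n, i0 + span_tr - 1L)
        rate[idx] <- rate[idx] + amp * ktr[seq_along(idx)]
      }
      if (sus != 0) {
        idx <- i0:min(n, i0 + span_su - 1L)
        rate[idx] <- rate[idx] + sus * ksu[seq_along(idx)]
      }
    }
  }
  pmax(rate, 0)
}

# Inhomogeneous-Poisson sampling by thinning against the rate profile
# (step function on the 1-ms grid).
sample_spikes_thinning <- function(rate, t_end_ms) {
  rmax <- max(rate)
  if (rmax <= 0) {
    warning("rate profile is zero everywhere; returning an empty train")
    return(numeric(0))
  }
  n_cand <- rpois(1, rmax * t_end_ms / 1000)
  if (n_cand == 0) return(numeric(0))
  cand <- sort(runif(n_cand, 0, t_end_ms))
  keep <- runif(n_cand) < rate[pmin(floor(cand) + 1L, length(rate))] / rmax
  sp <- cand[keep]
  # enforce 0.1-ms uniqueness
  if (length(sp) > 1) sp <- sp[c(TRUE, diff(sp) >= 0.1)]
  sp
}

#' Simulate a spike train for a trial table
#'
#' Draws an inhomogeneous-Poisson spike train (thinning against a 1-kHz
#' discretized rate profile) whose rate is the archetype baseline plus
#' difference-of-exponentials response kernels aligned to each trial's
#' target onset (or, for fixation sessions, each object onset). The
#' expected spike count in any window equals the integral of the rate
#' profile over that window.
#'
#' If the archetype has a nonzero `latency_coupling`, response amplitudes in
#' the coupled conditions are scaled by
#' `max(0, 1 + coupling * (rt - mean(rt)) / sd(rt))`, standardized within
#' each (value, direction) cell of the supplied trials.
#'
#' @param trials Trial table with `t_target_ms`, `value`, `direction`,
#'   `rt_ms` (or an object table with `t_object_ms`).
#' @param archetype A [neuron_archetype()].
#' @param seed Optional integer seed.
#' @param t_end_ms Recording end time; defaults to 1500 ms past the last event.
#' @param attenuation Amplitude multiplier (used for fixation sessions).
#' @return Sorted numeric vector of spike times, ms.
#' @export
simulate_spike_train <- function(trials, archetype, seed = NULL,
                                 t_end_ms = NULL, attenuation = 1) {
  if (!is.null(seed)) set.seed(seed)
  tcol <- if ("t_object_ms" %in% names(trials)) "t_object_ms" else "t_target_ms"
  ev <- trials[!is.na(trials[[tcol]]), , drop = FALSE]
  events <- data.frame(t_ms = ev[[tcol]], value = ev$value,
                       direction = ev$direction,
                       stringsAsFactors = FALSE)
  events$gain <- rep(1, nrow(events))
  if (archetype$latency_coupling != 0 && "rt_ms" %in% names(ev)) {
    cellkey <- paste(ev$value, ev$direction, sep = ".")
    for (cell in archetype$coupling_conditions) {
      in_cell <- cellkey == cell & !is.na(ev$rt_ms)
      if (sum(in_cell) >= 2) {
        z <- (ev$rt_ms[in_cell] - mean(ev$rt_ms[in_cell])) /
          sd(ev$rt_ms[in_cell])
        events$gain[in_cell] <-
          pmax(0, 1 + archetype$latency_coupling * z)
      }
    }
  }
  if (is.null(t_end_ms)) {
    t_end_ms <- (if (nrow(events)) max(events$t_ms) else 0) + 1500
  }
  rate <- session_rate_profile(events, archetype, t_end_ms,
                               attenuation = attenuation)
  sample_spikes_thinning(rate, t_end_ms)
}

# Per-neuron response gain: one log-normal draw scaling the whole
# amplitude structure of a session's archetype.
scale_archetype <- function(archetype, gain) {
  archetype$amplitude <- archetype$amplitude * gain
  archetype$sustain_amplitude <- archetype$sustain_amplitude * gain
  archetype
}

rtruncnorm1 <- function(n, mean, sd, lower, upper) {
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need) > 0) {
    draw <- rnorm(length(need), mean, sd)
    ok <- draw >= lower & draw <= upper
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Simulate a complete choice-task session
#'
#' Generates a full synthetic session: a trial schedule (preparatory
#' interval, scene onset, free viewing, fixation, target onset), condition
#' labels drawn uniformly over value and target position, actions drawn from
#' the behavioral policy, truncated-normal reaction times, and (optionally)
#' the implied eye trace and an archetype-driven spike train. Identical
#' inputs and seed reproduce the session exactly.
#'
#' @param task A [task_config()].
#' @param policy A [behavior_policy()].
#' @param archetype A [neuron_archetype()], or `NULL` to skip spikes.
#' @param n_trials Number of object presentations (each presentation is one
#'   trial record).
#' @param seed Integer seed.
#' @param monkey_id,neuron_id,region,hemisphere Session metadata. `region`
#'   is `"Cd"` or `"Put"`; `hemisphere` fixes the contra/ipsi convention
#'   (targets in the opposite hemifield are contralateral).
#' @param noise_sd Eye-position noise SD, degrees.
#' @param components Character subset of `c("eye", "spikes")` to synthesize;
#'   dropping `"eye"` makes large-population simulations cheap.
#' @param rt_bounds_ms Reaction-time truncation bounds.
#' @return An `ephys_session` list: metadata, `trials`, `spikes`, `eye`.
#' @export
simulate_choice_session <- function(task, policy, archetype = NULL,
                                    n_trials = 240, seed = 1,
                                    monkey_id = NULL, neuron_id = "n001",
                                    region = "Cd", hemisphere = "left",
                                    noise_sd = 0.05,
                                    components = c("eye", "spikes"),
                                    rt_bounds_ms = NULL) {
  if (n_trials < 1) stop("n_trials must be at least 1")
  validate_policy(policy)
  if (is.null(monkey_id)) {
    monkey_id <- attr(policy, "monkey")
    if (is.null(monkey_id)) monkey_id <- "C"
  }
  if (is.null(rt_bounds_ms)) {
    rt_bounds_ms <- attr(policy, "rt_bounds_ms")
    if (is.null(rt_bounds_ms)) rt_bounds_ms <- c(80, 600)
  }
  set.seed(seed)
  if (!is.null(archetype) && archetype$gain_sd > 0) {
    archetype <- scale_archetype(archetype,
                                 exp(rnorm(1, 0, archetype$gain_sd)))
  }
  actions <- c("Accept", "Return", "Stay", "Other", "FixBreak")
  scene <- sample.int(task$n_scenes, n_trials, replace = TRUE)
  value <- sample(c("good", "bad"), n_trials, replace = TRUE)
  angle <- sample(task$target_angles_deg, n_trials, replace = TRUE)
  direction <- ifelse(is_contra(angle, hemisphere), "contra", "ipsi")
  action <- character(n_trials)
  rt <- rep(NA_real_, n_trials)
  for (i in seq_len(n_trials)) {
    row <- policy[policy$scene == scene[i] & policy$value == value[i], ]
    p <- as.numeric(row[, paste0("p_", actions)])
    action[i] <- sample(actions, 1, prob = p)
    if (action[i] %in% c("Accept", "Return", "Other")) {
      rt[i] <- rtruncnorm1(1, row$rt_mean, row$rt_sd,
                           rt_bounds_ms[1], rt_bounds_ms[2])
    }
  }
  prep <- runif(n_trials, task$prep_interval_ms[1], task$prep_interval_ms[2])
  dwell <- runif(n_trials, 100, 300)       # return-back hold inside target
  t_break <- runif(n_trials, 100, task$fp_hold_ms - 100)
  t_scene <- t_fp <- t_target <- t_go <- t_back <- t_reward <-
    t_end <- rep(NA_real_, n_trials)
  cursor <- 2000                            # lead-in for baseline windows
  for (i in seq_len(n_trials)) {
    t_scene[i] <- cursor + prep[i]
    t_fp[i] <- t_scene[i] + task$scene_free_view_ms
    go_dur <- saccade_duration_ms(task$target_eccentricity_deg)
    if (action[i] == "FixBreak") {
      t_go[i] <- t_fp[i] + t_break[i]
      t_end[i] <- t_go[i] + 1000
    } else {
      t_target[i] <- t_fp[i] + task$fp_hold_ms
      if (action[i] %in% c("Accept", "Return", "Other")) {
        t_go[i] <- t_target[i] + rt[i]
      }
      if (action[i] == "Accept") {
        t_reward[i] <- t_go[i] + go_dur + task$accept_hold_ms
        t_end[i] <- t_reward[i] + 300
      } else if (action[i] == "Return") {
        t_back[i] <- t_go[i] + go_dur + dwell[i]
        t_end[i] <- t_target[i] + 1500
      } else {
        t_end[i] <- t_target[i] + 1500
      }
    }
    cursor <- t_end[i] + 500
  }
  trials <- data.frame(
    trial_id = seq_len(n_trials), scene = scene, value = value,
    direction = direction, angle_deg = angle, t_scene_ms = t_scene,
    t_fp_ms = t_fp, t_target_ms = t_target, t_saccade_go_ms = t_go,
    t_saccade_back_ms = t_back, action = factor(action, levels = actions),
    rt_ms = rt,
    reward = value == "good" & action == "Accept",
    t_end_ms = t_end, stringsAsFactors = FALSE)
  session <- list(monkey_id = monkey_id, neuron_id = neuron_id,
                  region = region, hemisphere = hemisphere, task = "choice",
                  seed = seed, config = task, trials = trials,
                  spikes = NULL, eye = NULL)
  if ("spikes" %in% components && !is.null(archetype)) {
    session$spikes <- simulate_spike_train(trials, archetype,
                                           t_end_ms = cursor + 500)
    session$archetype <- archetype$label
  }
  if ("eye" %in% components) {
    session$eye <- synthesize_eye_trace(trials, task, noise_sd = noise_sd)
  }
  class(session) <- "ephys_session"
  session
}

#' Simulate a fixation-task session
#'
#' Each trial presents the scene-1 good and bad objects alternately 2-4
#' times to one side of the fixation point (400 ms on, 400 ms interstimulus
#' interval) while the subject maintains central fixation; reward follows
#' the final object. Neuronal responses at object onset are attenuated by
#' the archetype's `fixation_attenuation`. A small fraction of trials break
#' fixation with a reflexive saccade toward the object.
#'
#' @inheritParams simulate_choice_session
#' @param p_fixbreak Probability that a trial ends with a fixation break.
#' @return An `ephys_session` with `task = "fixation"` and an `objects`
#'   table (one row per object presentation).
#' @export
simulate_fixation_session <- function(task, archetype = NULL, n_trials = 40,
                                      seed = 1, monkey_id = "C",
                                      neuron_id = "n001", region = "Cd",
                                      hemisphere = "left", noise_sd = 0.05,
                                      components = c("eye", "spikes"),
                                      p_fixbreak = 0.05) {
  if (n_trials < 1) stop("n_trials must be at least 1")
  set.seed(seed)
  if (!is.null(archetype) && archetype$gain_sd > 0) {
    archetype <- scale_archetype(archetype,
                                 exp(rnorm(1, 0, archetype$gain_sd)))
  }
  n_pres <- sample(2:4, n_trials, replace = TRUE)
  side <- sample(c(0, 180), n_trials, replace = TRUE)  # right / left of FP
  first_val <- sample(c("good", "bad"), n_trials, replace = TRUE)
  broke <- runif(n_trials) < p_fixbreak
  objects <- list()
  trials <- list()
  cursor <- 2000
  step <- task$fixation_object_ms + task$fixation_isi_ms
  for (i in seq_len(n_trials)) {
    t_scene <- cursor + runif(1, task$prep_interval_ms[1],
                              task$prep_interval_ms[2])
    t_fp <- t_scene + task$scene_free_view_ms
    t_first <- t_fp + task$fp_hold_ms
    k <- n_pres[i]
    vals <- rep(c(first_val[i],
                  setdiff(c("good", "bad"), first_val[i])),
                length.out = k)
    t_obj <- t_first + (seq_len(k) - 1) * step
    dir_i <- ifelse(is_contra(side[i], hemisphere), "contra", "ipsi")
    brk_at <- if (broke[i]) sample.int(k, 1) else NA_integer_
    if (!is.na(brk_at)) {
      vals <- vals[seq_len(brk_at)]
      t_obj <- t_obj[seq_len(brk_at)]
      k <- brk_at
    }
    objects[[i]] <- data.frame(
      trial_id = i, presentation = seq_len(k), value = vals,
      direction = dir_i, angle_deg = side[i], t_object_ms = t_obj,
      stringsAsFactors = FALSE)
    t_last_off <- t_obj[k] + task$fixation_object_ms
    t_end <- t_last_off + task$reward_delay_fixation_ms + 200
    trials[[i]] <- data.frame(
      trial_id = i, scene = 1L, value = NA_character_, direction = dir_i,
      angle_deg = side[i], t_scene_ms = t_scene, t_fp_ms = t_fp,
      t_target_ms = t_obj[1],
      t_saccade_go_ms = if (broke[i]) t_obj[k] + 150 else NA_real_,
      t_saccade_back_ms = NA_real_,
      action = factor(if (broke[i]) "FixBreak" else "Stay",
                      levels = c("Accept", "Return", "Stay", "Other",
                                 "FixBreak")),
      rt_ms = NA_real_, reward = !broke[i], t_end_ms = t_end,
      stringsAsFactors = FALSE)
    cursor <- t_end + 500
  }
  trials <- do.call(rbind, trials)
  objects <- do.call(rbind, objects)
  session <- list(monkey_id = monkey_id, neuron_id = neuron_id,
                  region = region, hemisphere = hemisphere,
                  task = "fixation", seed = seed, config = task,
                  trials = trials, objects = objects,
                  spikes = NULL, eye = NULL)
  if ("spikes" %in% components && !is.null(archetype)) {
    session$spikes <- simulate_spike_train(
      objects, archetype, t_end_ms = cursor + 500,
      attenuation = archetype$fixation_attenuation)
    session$archetype <- archetype$label
  }
  if ("eye" %in% components) {
    cmds_list <- lapply(which(broke), function(i) {
      tr <- trials[trials$trial_id == i, ]
      obj <- objects[objects$trial_id == i, ]
      last <- obj[nrow(obj), ]
      land <- target_position(last$angle_deg, 10)
      rbind(data.frame(t_ms = tr$t_saccade_go_ms, x_deg = land[1],
                       y_deg = land[2]),
            data.frame(t_ms = tr$t_saccade_go_ms + 500, x_deg = 0,
                       y_deg = 0))
    })
    cmds <- if (length(cmds_list)) do.call(rbind, cmds_list) else
      data.frame(t_ms = numeric(0), x_deg = numeric(0), y_deg = numeric(0))
    session$eye <- eye_trace_from_commands(
      cmds, max(trials$t_end_ms) + 1000, noise_sd = noise_sd)
  }
  class(session) <- "ephys_session"
  session
}

#' Simulate a long-format activity table
#'
#' Generates the per-neuron, per-condition mean-activity table that the
#' mixed-model stage consumes, directly from the Gaussian generating model:
#' cell means plus monkey and neuron random intercepts plus residual noise.
#' One row per neuron x condition cell. Used for mixed-model calibration
#' (type-I error, power, variance recovery).
#'
#' @param n_monkeys,n_neurons Number of monkeys and neurons per monkey.
#' @param cells Data frame of condition columns (factors); defaults to the
#'   full Scene x Value x Direction grid.
#' @param cell_means Numeric vector of length `nrow(cells)` (recycled):
#'   fixed-effect mean per cell. Zero for a null table.
#' @param sd_monkey,sd_neuron,sd_resid Random-intercept and residual SDs.
#' @param seed Integer seed.
#' @return Data frame with `NeuronalActivity`, the condition columns,
#'   `monkey_ID` and `Neuron_ID` (factors; neurons nested in monkeys).
#' @export
simulate_activity_table <- function(n_monkeys = 2, n_neurons = 60,
                                    cells = NULL, cell_means = 0,
                                    sd_monkey = 0.5, sd_neuron = 1,
                                    sd_resid = 1, seed = 1) {
  set.seed(seed)
  if (is.null(cells)) {
    cells <- expand.grid(Scene = factor(1:4),
                         Value = factor(c("good", "bad")),
                         Direction = factor(c("contra", "ipsi")))
  }
  q <- nrow(cells)
  mu <- rep_len(cell_means, q)
  monkeys <- paste0("M", seq_len(n_monkeys))
  a <- rnorm(n_monkeys, 0, sd_monkey)
  rows <- vector("list", n_monkeys * n_neurons)
  idx <- 0L
  for (m in seq_len(n_monkeys)) {
    b <- rnorm(n_neurons, 0, sd_neuron)
    for (j in seq_len(n_neurons)) {
      idx <- idx + 1L
      df <- cells
      df$NeuronalActivity <- mu + a[m] + b[j] + rnorm(q, 0, sd_resid)
      df$monkey_ID <- monkeys[m]
      df$Neuron_ID <- sprintf("%s_n%03d", monkeys[m], j)
      rows[[idx]] <- df
    }
  }
  out <- do.call(rbind, rows)
  out$monkey_ID <- factor(out$monkey_ID)
  out$Neuron_ID <- factor(out$Neuron_ID)
  rownames(out) <- NULL
  out
}
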