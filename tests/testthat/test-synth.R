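test_that("degenerate policy forces the commanded actions", {
  s <- simulate_choice_session(fix_task, degenerate_policy(), NULL,
                               n_trials = 10, seed = 1,
                               components = character(0))
  expect_equal(nrow(s$trials), 10)
  good <- s$trials$value == "good"
  expect_true(all(s$trials$action[good] == "Accept"))
  expect_true(all(s$trials$action[!good] == "Return"))
})

test_that("sessions are reproducible under a fixed seed", {
  s1 <- simulate_choice_session(fix_task, fix_policy_C,
                                neuron_archetype("cluster2_bad"),
                                n_trials = 30, seed = 7)
  s2 <- simulate_choice_session(fix_task, fix_policy_C,
                                neuron_archetype("cluster2_bad"),
                                n_trials = 30, seed = 7)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$spikes, s2$spikes)
  expect_identical(s1$eye, s2$eye)
  s3 <- simulate_choice_session(fix_task, fix_policy_C,
                                neuron_archetype("cluster2_bad"),
                                n_trials = 30, seed = 8)
  expect_false(identical(s1$spikes, s3$spikes))
})

test_that("empirical action frequencies match the policy marginals", {
  s <- simulate_choice_session(fix_task, fix_policy_C, NULL,
                               n_trials = 3000, seed = 7,
                               components = character(0))
  bad <- s$trials[s$trials$value == "bad", ]
  # per-scene Return probability follows the printed counts
  for (sc in 1:4) {
    sub <- bad[bad$scene == sc, ]
    p <- fix_policy_C$p_Return[fix_policy_C$scene == sc &
                                 fix_policy_C$value == "bad"]
    se <- sqrt(p * (1 - p) / nrow(sub))
    expect_lt(abs(mean(sub$action == "Return") - p), 3 * se)
  }
})

test_that("simulated reaction times match the printed table parameters", {
  s <- simulate_choice_session(fix_task, fix_policy_C, NULL,
                               n_trials = 4000, seed = 11,
                               components = character(0))
  tr <- s$trials
  g1 <- tr$rt_ms[tr$value == "good" & tr$scene == 1 & !is.na(tr$rt_ms)]
  expect_gt(length(g1), 100)
  expect_lt(abs(mean(g1) - 160.9), 3 * 21.6 / sqrt(length(g1)))
  b1 <- tr$rt_ms[tr$value == "bad" & tr$scene == 1 & tr$action == "Return"]
  expect_lt(abs(mean(b1) - 234.3), 3 * 46.7 / sqrt(length(b1)))
})

test_that("policy validation rejects a broken simplex", {
  pol <- behavior_policy("C")
  pol$p_Return[1] <- pol$p_Return[1] + 0.01
  expect_error(
    simulate_choice_session(fix_task, pol, NULL, n_trials = 5, seed = 1),
    "sum to 1")
  expect_error(
    simulate_choice_session(fix_task, fix_policy_C, NULL, n_trials = 0,
                            seed = 1),
    "at least 1")
})

test_that("homogeneous spike trains are Poisson-calibrated", {
  arch <- neuron_archetype("cluster3_visual", baseline_rate = 5,
                           amplitude = matrix(0, 2, 2,
                             dimnames = list(c("good", "bad"),
                                             c("contra", "ipsi"))),
                           sustain_amplitude = c(good = 0, bad = 0),
                           gain_sd = 0)
  empty <- data.frame(t_target_ms = numeric(0), value = character(0),
                      direction = character(0), rt_ms = numeric(0))
  sp <- simulate_spike_train(empty, arch, seed = 3, t_end_ms = 100000)
  expect_lt(abs(length(sp) - 500), 3 * sqrt(500))
  expect_true(all(diff(sp) >= 0.1 - 1e-12))
})

test_that("expected counts in a response window match the rate integral", {
  arch <- neuron_archetype("cluster2_bad", gain_sd = 0)
  trials <- data.frame(t_target_ms = 2000 + (0:39) * 3000,
                       value = "bad", direction = "contra",
                       rt_ms = NA_real_)
  rate <- choicephys:::session_rate_profile(
    data.frame(t_ms = trials$t_target_ms, value = trials$value,
               direction = trials$direction, gain = 1),
    arch, 2000 + 40 * 3000)
  win <- c(100, 300)
  expected <- sum(vapply(trials$t_target_ms, function(ev) {
    sum(rate[(ev + win[1]):(ev + win[2] - 1) + 1]) / 1000
  }, numeric(1)))
  counts <- vapply(1:30, function(s) {
    sp <- simulate_spike_train(trials, arch, seed = 200 + s,
                               t_end_ms = 2000 + 40 * 3000)
    sum(vapply(trials$t_target_ms, function(ev) {
      sum(sp >= ev + win[1] & sp < ev + win[2])
    }, numeric(1)))
  }, numeric(1))
  se <- sqrt(expected / 30)
  expect_lt(abs(mean(counts) - expected), 3 * se)
})

test_that("bad-preferring archetype orders window rates as designed", {
  s <- quick_session("cluster2_bad", seed = 21, n_trials = 200)
  tr <- s$trials
  keep <- !is.na(tr$t_target_ms) & tr$direction == "contra"
  act <- trial_window_activity(s$spikes, tr$t_target_ms[keep])
  val <- tr$value[keep]
  expect_gt(mean(act$rate[val == "bad"]), mean(act$rate[val == "good"]))
})

test_that("eye traces hold fixation and embed detectable saccades", {
  quiet <- eye_trace_from_commands(NULL, 1000, noise_sd = 0)
  expect_true(all(eye_speed(quiet) <= 1e-9))
  one <- eye_trace_from_commands(
    data.frame(t_ms = 200, x_deg = 15, y_deg = 0), 600, noise_sd = 0)
  onset <- detect_saccade(one, 0, search_window = 400)
  expect_lte(abs(onset - 200), 2)
  # peak speed scales with amplitude and clears the threshold
  spd15 <- max(eye_speed(one))
  five <- eye_trace_from_commands(
    data.frame(t_ms = 200, x_deg = 5, y_deg = 0), 600, noise_sd = 0)
  expect_gt(spd15, max(eye_speed(five)))
  expect_gt(max(eye_speed(five)), 40)
  expect_error(
    eye_trace_from_commands(
      data.frame(t_ms = c(200, 205), x_deg = c(15, 0), y_deg = 0), 600),
    "overlapping")
})

test_that("fixation sessions present 2-4 alternating objects", {
  s <- simulate_fixation_session(fix_task, NULL, n_trials = 50, seed = 3,
                                 p_fixbreak = 0, components = character(0))
  per_trial <- table(s$objects$trial_id)
  expect_true(all(per_trial >= 2 & per_trial <= 4))
  # alternation: consecutive presentations differ in value
  for (id in unique(s$objects$trial_id)) {
    v <- s$objects$value[s$objects$trial_id == id]
    expect_true(all(v[-1] != v[-length(v)]))
  }
})

test_that("fixation attenuation scales the evoked response", {
  arch0 <- neuron_archetype("cluster2_bad", fixation_attenuation = 0,
                            gain_sd = 0)
  s0 <- simulate_fixation_session(fix_task, arch0, n_trials = 60, seed = 5,
                                  p_fixbreak = 0, components = "spikes")
  act0 <- trial_window_activity(s0$spikes, s0$objects$t_object_ms)
  se0 <- sd(act0$z) / sqrt(length(act0$z))
  expect_lt(abs(mean(act0$z)), 3 * se0)

  arch1 <- neuron_archetype("cluster2_bad", fixation_attenuation = 1,
                            gain_sd = 0)
  s1 <- simulate_fixation_session(fix_task, arch1, n_trials = 60, seed = 5,
                                  p_fixbreak = 0, components = "spikes")
  sc <- simulate_choice_session(fix_task, fix_policy_C, arch1,
                                n_trials = 200, seed = 6,
                                components = "spikes")
  keep <- !is.na(sc$trials$t_target_ms) & sc$trials$value == "bad" &
    sc$trials$direction == "contra"
  act_c <- trial_window_activity(sc$spikes, sc$trials$t_target_ms[keep])
  fobj <- s1$objects[s1$objects$value == "bad" &
                       s1$objects$direction == "contra", ]
  act_f <- trial_window_activity(s1$spikes, fobj$t_object_ms)
  # full-strength fixation responses are indistinguishable from choice
  expect_gt(t.test(act_c$rate, act_f$rate)$p.value, 0.001)
})

test_that("session bundles round-trip through disk exactly", {
  s <- simulate_choice_session(fix_task, fix_policy_C,
                               neuron_archetype("cluster1_good"),
                               n_trials = 12, seed = 9, noise_sd = 0.02)
  dir <- file.path(tempdir(), "session_rt")
  write_session(s, dir)
  s2 <- read_session(dir)
  expect_equal(s2$trials$t_target_ms, s$trials$t_target_ms)
  expect_equal(s2$trials$action, s$trials$action)
  expect_equal(s2$spikes, s$spikes, tolerance = 1e-12)
  expect_equal(s2$eye$x_deg, s$eye$x_deg, tolerance = 1e-12)
  expect_equal(s2$monkey_id, s$monkey_id)
  expect_equal(s2$config$target_eccentricity_deg,
               s$config$target_eccentricity_deg)
  unlink(dir, recursive = TRUE)
})

test_that("activity-table generator reproduces its generating moments", {
  tab <- simulate_activity_table(2, 40, cell_means = 1.5, sd_monkey = 0,
                                 sd_neuron = 0, sd_resid = 1, seed = 4)
  expect_equal(nrow(tab), 2 * 40 * 16)
  expect_lt(abs(mean(tab$NeuronalActivity) - 1.5),
            3 / sqrt(nrow(tab)))
})
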