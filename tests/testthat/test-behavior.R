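test_that("saccade detection respects the velocity threshold", {
  still <- eye_trace_from_commands(NULL, 600, noise_sd = 0)
  expect_true(is.na(detect_saccade(still, 0)))
  # a ramp at 39 deg/s stays below threshold; 41 deg/s crosses
  ramp <- function(v_deg_s) {
    tt <- 0:600
    data.frame(t_ms = tt, x_deg = pmin(tt, 400) * v_deg_s / 1000,
               y_deg = 0) |>
      structure(class = c("eye_trace", "data.frame"))
  }
  expect_true(is.na(detect_saccade(ramp(39), 0)))
  expect_false(is.na(detect_saccade(ramp(41), 0)))
  # synthetic 15-degree saccade at +180 ms recovered within 2 ms
  tr <- eye_trace_from_commands(
    data.frame(t_ms = 180, x_deg = 15, y_deg = 0), 600, noise_sd = 0)
  expect_lte(abs(detect_saccade(tr, 0) - 180), 2)
})

test_that("action classification follows the gaze geometry rules", {
  tgt <- c(15, 0)
  # saccade into the target square, held >= 400 ms: Accept
  acc <- eye_trace_from_commands(
    rbind(data.frame(t_ms = 200, x_deg = 15, y_deg = 0),
          data.frame(t_ms = 750, x_deg = 0, y_deg = 0)), 1400)
  expect_equal(classify_action(acc, tgt, t_target = 0), "Accept")
  # dwell 150 ms then back to center: Return
  ret <- eye_trace_from_commands(
    rbind(data.frame(t_ms = 200, x_deg = 15, y_deg = 0),
          data.frame(t_ms = 200 + 43 + 150, x_deg = 0, y_deg = 0)), 1400)
  expect_equal(classify_action(ret, tgt, t_target = 0), "Return")
  # gaze within 1 degree of center throughout: Stay
  stay <- eye_trace_from_commands(NULL, 1400, noise_sd = 0,
                                  start = c(0.7, 0.7))
  expect_equal(classify_action(stay, tgt, t_target = 0), "Stay")
  # saccade away from the target: Other
  oth <- eye_trace_from_commands(
    data.frame(t_ms = 200, x_deg = 0, y_deg = 15), 1400)
  expect_equal(classify_action(oth, tgt, t_target = 0), "Other")
  expect_error(classify_action(acc, NULL, t_target = 0), "geometry")
})

test_that("classification agrees with commanded actions, noisy or not", {
  agree <- function(noise_sd, seed, n) {
    s <- simulate_choice_session(fix_task, fix_policy_C, NULL,
                                 n_trials = n, seed = seed,
                                 noise_sd = noise_sd,
                                 components = "eye")
    mean(classify_session_actions(s) == as.character(s$trials$action))
  }
  expect_equal(agree(0, 31, 120), 1)
  expect_gte(agree(0.3, 33, 200), 0.98)
})

test_that("action summaries reproduce the printed percentages", {
  trials <- expand_action_counts(action_count_table())
  bs <- summarize_actions(trials)
  ac <- bs$action_counts
  row <- function(m, sc) ac[ac$monkey == m & ac$scene == sc, ]
  expect_equal(row("C", "1")$pct_Return, 75.3)
  expect_equal(row("C", "1")$Stay, 314)
  expect_equal(row("C", "nonswitch")$Stay, 598)
  expect_equal(row("C", "nonswitch")$total, 2888)
  expect_equal(row("S", "2")$pct_Stay, 28.3)
  # single-trial degenerate case
  one <- data.frame(monkey_id = "C", scene = 1, value = "bad",
                    action = "Stay")
  expect_equal(summarize_actions(one)$action_counts$pct_Stay[1], 100.0)
})

test_that("Welch test matches the textbook formula", {
  same <- c(5, 6, 7, 8)
  res <- compare_rt_welch(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p, 1)
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  res <- compare_rt_welch(x, y)
  orc <- oracle_welch(x, y)
  expect_equal(res$t, orc$t, tolerance = 1e-10)
  expect_equal(res$df, orc$df, tolerance = 1e-10)
  expect_equal(res$p, orc$p, tolerance = 1e-10)
  expect_error(compare_rt_welch(1, y), "at least two")
})

test_that("good-object saccades are much faster than return-go saccades", {
  s <- simulate_choice_session(fix_task, fix_policy_C, NULL,
                               n_trials = 2500, seed = 17,
                               components = character(0))
  tr <- s$trials[s$trials$scene == 1, ]
  good <- tr$rt_ms[tr$value == "good" & !is.na(tr$rt_ms)]
  bad <- tr$rt_ms[tr$value == "bad" & tr$action == "Return"]
  res <- compare_rt_welch(good, bad)
  expect_lt(res$p, 1e-10)
  expect_lt(res$t, 0)
})

test_that("Fisher test and phi match enumeration and closed form", {
  flat <- stay_proportion_test(c(10, 10), c(10, 10))
  expect_equal(flat$phi, 0)
  expect_equal(flat$p_fisher, 1)
  perfect <- stay_proportion_test(c(7, 0), c(0, 7))
  expect_equal(perfect$phi, 1)
  # printed pooled counts, stay vs return
  res <- stay_proportion_test(c(598, 2213), c(261, 2535))
  tab <- rbind(c(598, 2213), c(261, 2535))
  expect_equal(res$phi, oracle_phi(tab), tolerance = 1e-12)
  expect_equal(res$p_fisher, oracle_fisher_p(tab), tolerance = 1e-8)
  expect_error(stay_proportion_test(c(0, 0), c(1, 2)), "zero margin")
})

test_that("stay-table construction supports both poolings", {
  counts <- action_count_table()
  cc <- counts[counts$monkey == "C", ]
  tab_sr <- stay_table(cc, "stay-vs-return")
  expect_equal(unname(tab_sr["nonswitch", ]), c(598, 2213))
  tab_sa <- stay_table(cc, "stay-vs-all")
  expect_equal(unname(tab_sa["nonswitch", ]), c(598, 2888 - 598))
  # the two constructions bracket the printed effect sizes
  phi_sr <- stay_proportion_test(tab_sr[1, ], tab_sr[2, ])$phi
  ss <- stay_table(counts[counts$monkey == "S", ], "stay-vs-all")
  phi_sa <- stay_proportion_test(ss[1, ], ss[2, ])$phi
  expect_equal(round(phi_sr, 2), 0.17)
  expect_equal(round(phi_sa, 2), 0.07)
})

test_that("exhaustive small-table agreement between fisher.test and the oracle", {
  set.seed(42)
  for (rep in 1:40) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2)
    if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) next
    res <- stay_proportion_test(tab[1, ], tab[2, ])
    expect_equal(res$p_fisher, oracle_fisher_p(tab), tolerance = 1e-8)
    expect_equal(res$phi, oracle_phi(tab), tolerance = 1e-12)
  }
})
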