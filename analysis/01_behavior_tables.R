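#!/usr/bin/env Rscript
# Behavioral summaries.
#
# Reproduces the printed action-frequency percentages and stay-proportion
# tests from the published count table, then validates the full detection
# chain (eye trace -> saccade detection -> action classification ->
# summary) on a simulated session with known commanded actions.

suppressMessages(library(choicephys))
out <- "results/behavior"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

## printed counts -> percentages -----------------------------------------
counts <- action_count_table()
summary_printed <- summarize_actions(expand_action_counts(counts))
write.table(summary_printed$action_counts,
            file.path(out, "behavior_summary.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("Monkey C Return percentages (scenes 1-4):",
    summary_printed$action_counts$pct_Return[1:4], "\n")

tests <- list()
for (m in c("C", "S")) {
  for (mode in c("stay-vs-return", "stay-vs-all")) {
    tab <- stay_table(counts[counts$monkey == m, ], mode)
    res <- stay_proportion_test(tab[1, ], tab[2, ])
    tests[[paste(m, mode, sep = "_")]] <-
      list(p_fisher = res$p_fisher, phi = res$phi)
    cat(sprintf("monkey %s, %s: phi = %.3f, p = %.3g\n", m, mode,
                res$phi, res$p_fisher))
  }
}

## simulated sessions: classification agreement and RT tests -------------
task <- task_config()
s <- simulate_choice_session(task, behavior_policy("C"), NULL,
                             n_trials = 400, seed = 1, noise_sd = 0.05,
                             components = "eye")
classified <- classify_session_actions(s)
agreement <- mean(classified == as.character(s$trials$action))
cat(sprintf("classifier agreement with commanded actions: %.1f%%\n",
            100 * agreement))

big <- simulate_choice_session(task, behavior_policy("C"), NULL,
                               n_trials = 8000, seed = 2,
                               components = character(0))
welch <- lapply(1:4, function(sc) {
  tr <- big$trials[big$trials$scene == sc, ]
  res <- compare_rt_welch(tr$rt_ms[tr$value == "good" & !is.na(tr$rt_ms)],
                          tr$rt_ms[tr$value == "bad" &
                                     tr$action == "Return"])
  cat(sprintf("scene %d: good %.1f ms vs bad %.1f ms, t = %.1f\n",
              sc, res$means[["good"]], res$means[["bad"]], res$t))
  list(scene = sc, t = res$t, df = res$df, p = res$p,
       mean_good = res$means[["good"]], mean_bad = res$means[["bad"]])
})

writeLines(jsonlite::toJSON(list(stay_tests = tests, welch = welch,
                                 classifier_agreement = agreement),
                            auto_unbox = TRUE, digits = NA),
           file.path(out, "behavior_tests.json"))
cat("wrote", file.path(out, "behavior_summary.tsv"), "\n")
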