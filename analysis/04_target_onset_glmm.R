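#!/usr/bin/env Rscript
# Mixed-model comparisons at scene and target onset.
#
# For each cluster: the cell-mean Z activity table (Scene x Value x
# Direction at target onset; Scene at scene onset), the parametric-
# bootstrap comparison of the full against the intercept-only model, and
# the Bonferroni-corrected post-hoc contrasts (family m = 12: six
# good-versus-bad tests per scene plus six across-scene tests).

suppressMessages(library(choicephys))
out <- "results/glmm"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sessions <- lapply(list.dirs("results/population/sessions",
                             recursive = FALSE), read_session)
clusters <- read.delim("results/cluster/clusters.tsv")
stopifnot(nrow(clusters) == length(sessions))

n_boot <- 999
comparisons <- list()
posthocs <- list()
for (cl in sort(unique(clusters$cluster))) {
  members <- which(clusters$cluster == cl)
  if (length(members) < 10) next
  tab_t <- activity_table(sessions[members], "target_onset")
  tab_s <- activity_table(sessions[members], "scene_onset")
  cmp_t <- parametric_bootstrap_compare(tab_t,
                                        full = ~ Scene * Value * Direction,
                                        null = ~ 1, n_boot = n_boot,
                                        seed = 100 + cl)
  cmp_s <- parametric_bootstrap_compare(tab_s, full = ~ Scene, null = ~ 1,
                                        n_boot = n_boot, seed = 200 + cl)
  cat(sprintf("cluster %d (n = %d): target-onset p = %.4g (%s engine), scene-onset p = %.3g\n",
              cl, length(members), cmp_t$p_boot, cmp_t$engine,
              cmp_s$p_boot))
  ph <- posthoc_pairwise(fit_lmm(tab_t, ~ Scene * Value * Direction),
                         ~ Value * Direction | Scene, m = 12)
  ph$cluster <- cl
  posthocs[[as.character(cl)]] <- ph
  comparisons[[paste0("cluster", cl)]] <- list(
    n_neurons = length(members),
    target_onset = list(p_boot = cmp_t$p_boot,
                        observed_diff = cmp_t$observed_diff,
                        n_boot = n_boot, engine = cmp_t$engine),
    scene_onset = list(p_boot = cmp_s$p_boot,
                       observed_diff = cmp_s$observed_diff,
                       n_boot = n_boot, engine = cmp_s$engine))
}

writeLines(jsonlite::toJSON(comparisons, auto_unbox = TRUE, digits = NA),
           file.path(out, "model_comparison.json"))
write.table(do.call(rbind, posthocs), file.path(out, "posthoc_table.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
cat("wrote", file.path(out, "model_comparison.json"), "\n")
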