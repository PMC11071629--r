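#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end synthetic analysis: the master
#' seed, population composition, per-session trial counts, bootstrap size,
#' cluster-count mode and the analysis-window presets. The defaults are
#' the study conditions the generator emulates; tests use reduced sizes.
#'
#' @param seed Master seed; every stage derives its own substream from it.
#' @param n_neurons Named integer vector: neurons per archetype.
#' @param n_trials_choice,n_trials_fixation Trials per session.
#' @param n_boot Parametric-bootstrap replicates for model comparisons.
#' @param k_mode `"auto"` (silhouette scan) or a fixed integer.
#' @param phi_mode Table construction for the stay-proportion test.
#' @param windows Named window presets, see [analysis_windows()].
#' @param noise_sd Eye-trace noise SD, degrees.
#' @param with_eye Synthesize eye traces (slow for large populations;
#'   behavioral classification falls back to commanded actions without).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 42,
                            n_neurons = default_population(),
                            n_trials_choice = 320,
                            n_trials_fixation = 48,
                            n_boot = 199,
                            k_mode = "auto",
                            phi_mode = "stay-vs-return",
                            windows = analysis_windows(),
                            noise_sd = 0.05,
                            with_eye = FALSE) {
  cfg <- list(seed = seed, n_neurons = n_neurons,
              n_trials_choice = n_trials_choice,
              n_trials_fixation = n_trials_fixation, n_boot = n_boot,
              k_mode = k_mode, phi_mode = phi_mode, windows = windows,
              noise_sd = noise_sd, with_eye = with_eye)
  class(cfg) <- "pipeline_config"
  cfg
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                              digits = NA), tmp)
  unname(md5sum(tmp))
}

derive_seed <- function(seed, idx) {
  as.integer((as.double(seed) * 7919 + idx * 104729) %% 2147483647)
}

#' Simulate the full synthetic neuron population
#'
#' One choice-task session (and one fixation-task session) per neuron,
#' with neurons alternating between the two monkeys (and their respective
#' behavioral policies) and archetypes mixed per `config$n_neurons`.
#'
#' @param config A [pipeline_config()].
#' @return List with `choice` and `fixation` session lists.
#' @export
simulate_population <- function(config) {
  task <- task_config()
  policies <- list(C = behavior_policy("C"), S = behavior_policy("S"))
  choice <- list()
  fixation <- list()
  idx <- 0L
  components <- c(if (config$with_eye) "eye", "spikes")
  for (arch_label in names(config$n_neurons)) {
    arch <- neuron_archetype(arch_label)
    for (j in seq_len(config$n_neurons[[arch_label]])) {
      idx <- idx + 1L
      monkey <- if (idx %% 2 == 1) "C" else "S"
      nid <- sprintf("%s%03d", substr(arch_label, 8, 8), j)
      choice[[idx]] <- simulate_choice_session(
        task, policies[[monkey]], arch,
        n_trials = config$n_trials_choice,
        seed = derive_seed(config$seed, idx), monkey_id = monkey,
        neuron_id = nid, noise_sd = config$noise_sd,
        components = components)
      fixation[[idx]] <- simulate_fixation_session(
        task, arch, n_trials = config$n_trials_fixation,
        seed = derive_seed(config$seed, idx + 100000L),
        monkey_id = monkey, neuron_id = nid,
        noise_sd = config$noise_sd, components = components)
    }
  }
  list(choice = choice, fixation = fixation)
}

#' Proactive-versus-reactive rejection contrast
#'
#' For each cluster and target side, compares the Z-scored object-window
#' activity across four cells: scene-1 bad objects rejected by Return,
#' scene-1 bad objects rejected by Stay (choice task, proactive
#' inhibition), and good and bad object presentations during the fixation
#' task (reactive inhibition). A parametric-bootstrap model comparison
#' gates six Bonferroni-corrected pairwise contrasts; the qualitative
#' flags (`return_vs_stay_ns`, `choice_gt_fixation`) are derived from the
#' post-hoc table only.
#'
#' @param choice_sessions,fixation_sessions Session lists (matched order,
#'   one per neuron).
#' @param cluster_labels Integer cluster label per neuron.
#' @param window Analysis window, ms post object onset.
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param min_trials Minimum trials per cell; neurons missing a cell are
#'   dropped from that contrast.
#' @param min_neurons Below this many complete neurons the population test
#'   is skipped (cell means are still reported).
#' @return A `contrast_report`: per cluster x side, cell means, the model
#'   comparison, the post-hoc table, and the qualitative flags.
#' @export
reject_mode_contrast <- function(choice_sessions, fixation_sessions,
                                 cluster_labels, window = c(100, 300),
                                 n_boot = 199, seed = 1, min_trials = 2,
                                 min_neurons = 10) {
  cells <- c("choice_return", "choice_stay", "fix_good", "fix_bad")
  reports <- list()
  for (cl in sort(unique(cluster_labels))) {
    sel <- which(cluster_labels == cl)
    for (side in c("contra", "ipsi")) {
      rows <- list()
      for (i in sel) {
        cs <- choice_sessions[[i]]
        fs <- fixation_sessions[[i]]
        tr <- cs$trials
        keep <- !is.na(tr$t_target_ms) & tr$scene == 1 &
          tr$value == "bad" & tr$direction == side &
          tr$action %in% c("Return", "Stay")
        obj <- fs$objects[fs$objects$direction == side, ]
        ev_choice <- tr$t_target_ms[keep]
        if (length(ev_choice) == 0L || nrow(obj) == 0L) next
        act_c <- trial_window_activity(cs$spikes, ev_choice,
                                       window = window)
        act_f <- trial_window_activity(fs$spikes, obj$t_object_ms,
                                       window = window)
        if (act_c$baseline$degenerate || act_f$baseline$degenerate) next
        lab <- as.character(tr$action[keep])
        vals <- c(choice_return = mean(act_c$z[lab == "Return"]),
                  choice_stay = mean(act_c$z[lab == "Stay"]),
                  fix_good = mean(act_f$z[obj$value == "good"]),
                  fix_bad = mean(act_f$z[obj$value == "bad"]))
        ns <- c(sum(lab == "Return"), sum(lab == "Stay"),
                sum(obj$value == "good"), sum(obj$value == "bad"))
        if (any(ns < min_trials) || any(!is.finite(vals))) next
        rows[[length(rows) + 1L]] <- data.frame(
          NeuronalActivity = as.numeric(vals),
          Cell = factor(cells, levels = cells),
          monkey_ID = cs$monkey_id,
          Neuron_ID = paste(cs$monkey_id, cs$neuron_id, sep = "_"),
          stringsAsFactors = FALSE)
      }
      if (length(rows) == 0L) next
      tab <- do.call(rbind, rows)
      tab$monkey_ID <- factor(tab$monkey_ID)
      tab$Neuron_ID <- factor(tab$Neuron_ID)
      cell_means <- tapply(tab$NeuronalActivity, tab$Cell, mean)
      entry <- list(cluster = cl, side = side,
                    n_neurons = nlevels(droplevels(tab$Neuron_ID)),
                    cell_means = cell_means, skipped = FALSE)
      if (entry$n_neurons < min_neurons) {
        entry$skipped <- TRUE
        entry$note <- "too few complete neurons; population test skipped"
      } else {
        cmp <- parametric_bootstrap_compare(
          tab, full = ~ Cell, null = ~ 1, n_boot = n_boot,
          seed = derive_seed(seed, cl * 10 + (side == "ipsi")))
        fit <- fit_lmm(tab, ~ Cell)
        ph <- posthoc_pairwise(fit, ~ Cell, m = 6)
        pick <- function(c1, c2) {
          hit <- grepl(c1, ph$contrast) & grepl(c2, ph$contrast)
          ph[hit, , drop = FALSE]
        }
        rs <- pick("choice_return", "choice_stay")
        # task effect isolated on value-matched cells: the same bad
        # objects, rejected in the choice task versus viewed passively
        # in the fixation task
        cf <- ph[(grepl("choice", ph$contrast) &
                    grepl("fix_bad", ph$contrast)), , drop = FALSE]
        entry$comparison <- cmp
        entry$posthoc <- ph
        entry$return_vs_stay_ns <-
          nrow(rs) == 1 && !rs$significant
        entry$choice_gt_fixation <-
          any(cf$significant & cf$effect_size > 0)
      }
      reports[[paste0("cluster", cl, "_", side)]] <- entry
    }
  }
  structure(reports, class = "contrast_report")
}

#' Run the full analysis pipeline on synthetic data
#'
#' Orchestrates every stage: population simulation, neuron inclusion
#' filtering, behavioral summary and tests, response-feature clustering,
#' per-cluster mixed-model comparisons at scene and target onset, the
#' latency-quartile correlation analysis, and the proactive-versus-
#' reactive rejection contrast. Deterministic under a fixed config.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory; when given, all stage tables
#'   are written (TSV/JSON) together with `report.md` and a `manifest.json`
#'   of file hashes.
#' @return A `pipeline_result` list with each stage's outputs.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  pop <- simulate_population(config)
  included <- vapply(pop$choice, inclusion_filter, logical(1))
  choice <- pop$choice[included]
  fixation <- pop$fixation[included]

  trials <- do.call(rbind, lapply(choice, function(s) {
    cbind(s$trials, monkey_id = s$monkey_id)
  }))
  behavior <- summarize_actions(trials)
  stay_tests <- lapply(c("C", "S"), function(m) {
    counts <- behavior$action_counts
    counts <- counts[counts$monkey == m & counts$scene %in% 1:4, ]
    counts$scene <- as.numeric(counts$scene)
    tab <- stay_table(counts, mode = config$phi_mode)
    stay_proportion_test(tab[1, ], tab[2, ])
  })
  names(stay_tests) <- c("C", "S")

  features <- build_features(choice, window = config$windows$target)
  if (identical(config$k_mode, "auto")) {
    ksel <- select_k(features, k_range = 2:8,
                     seed = derive_seed(config$seed, 2))
    k <- ksel$k_best
  } else {
    k <- as.integer(config$k_mode)
    ksel <- NULL
  }
  clust <- kmeans_assign(features, k = k,
                         seed = derive_seed(config$seed, 3))

  comparisons <- list()
  for (cl in seq_len(min(k, 3))) {
    in_cl <- which(clust$labels == cl)
    if (length(in_cl) < 10) next
    tab_target <- activity_table(choice[in_cl], "target_onset",
                                 window = config$windows$target)
    tab_scene <- activity_table(choice[in_cl], "scene_onset",
                                window = config$windows$scene)
    comparisons[[paste0("cluster", cl)]] <- list(
      target_onset = parametric_bootstrap_compare(
        tab_target, full = ~ Scene * Value * Direction, null = ~ 1,
        n_boot = config$n_boot, seed = derive_seed(config$seed, 10 + cl)),
      scene_onset = parametric_bootstrap_compare(
        tab_scene, full = ~ Scene, null = ~ 1,
        n_boot = config$n_boot, seed = derive_seed(config$seed, 20 + cl)),
      posthoc_target = posthoc_pairwise(
        fit_lmm(tab_target, ~ Scene * Value * Direction),
        ~ Value * Direction | Scene, m = 12))
  }

  latency <- tryCatch({
    cl1 <- which(clust$labels == 1)
    if (length(cl1) >= 6) {
      latency_correlation_analysis(choice[cl1],
                                   window = config$windows$target)
    } else NULL
  }, error = function(e) NULL)

  contrast <- reject_mode_contrast(choice, fixation, clust$labels,
                                   window = config$windows$object,
                                   n_boot = config$n_boot,
                                   seed = derive_seed(config$seed, 30))

  result <- list(config = config, config_hash = config_hash(config),
                 n_included = sum(included), behavior = behavior,
                 stay_tests = stay_tests, features = features,
                 k_selection = ksel, clusters = clust,
                 comparisons = comparisons, latency = latency,
                 contrast = contrast)
  class(result) <- "pipeline_result"
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name) {
    write.table(df, file.path(out_dir, name), sep = "\t",
                row.names = FALSE, quote = FALSE, na = "")
  }
  w(result$behavior$action_counts, "behavior_summary.tsv")
  if (!is.null(result$behavior$rt_stats)) {
    w(result$behavior$rt_stats, "behavior_rt.tsv")
  }
  wj <- function(x, name) {
    writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA,
                                null = "null", force = TRUE),
               file.path(out_dir, name))
  }
  wj(lapply(result$stay_tests, function(t) {
    list(p_fisher = t$p_fisher, phi = t$phi)
  }), "behavior_tests.json")
  clusters_df <- cbind(result$features,
                       cluster = result$clusters$labels)
  w(clusters_df, "clusters.tsv")
  if (!is.null(result$k_selection)) {
    wj(list(k_best = result$k_selection$k_best,
            silhouette_by_k = as.list(result$k_selection$silhouette_by_k)),
       "silhouette.json")
  }
  wj(lapply(result$comparisons, function(cc) {
    lapply(cc[c("target_onset", "scene_onset")], function(mc) {
      list(deviance_full = mc$deviance_full,
           deviance_null = mc$deviance_null,
           observed_diff = mc$observed_diff, p_boot = mc$p_boot,
           n_boot = mc$n_boot, engine = mc$engine)
    })
  }), "model_comparison.json")
  ph <- do.call(rbind, lapply(names(result$comparisons), function(nm) {
    df <- result$comparisons[[nm]]$posthoc_target
    df$cluster <- nm
    df
  }))
  if (!is.null(ph)) w(ph, "posthoc_table.tsv")
  if (!is.null(result$latency)) {
    w(result$latency$per_neuron, "latency_correlation.tsv")
    wj(result$latency$tests, "latency_test.json")
  }
  wj(lapply(unclass(result$contrast), function(e) {
    keep <- list(cluster = e$cluster, side = e$side,
                 n_neurons = e$n_neurons,
                 cell_means = as.list(e$cell_means),
                 skipped = e$skipped)
    if (!e$skipped) {
      keep$p_boot <- e$comparison$p_boot
      keep$return_vs_stay_ns <- e$return_vs_stay_ns
      keep$choice_gt_fixation <- e$choice_gt_fixation
    }
    keep
  }), "contrast_report.json")
  report <- c(
    "# Synthetic accept/reject pipeline report",
    "",
    sprintf("Config hash: %s", result$config_hash),
    sprintf("Neurons simulated: %d; passing inclusion filter: %d",
            sum(result$config$n_neurons), result$n_included),
    sprintf("Selected k: %d (silhouette %.3f)", result$clusters$k,
            result$clusters$silhouette),
    "",
    "Cluster sizes:",
    paste(sprintf("  cluster %d: %d", seq_len(result$clusters$k),
                  tabulate(result$clusters$labels,
                           result$clusters$k)), collapse = "\n"),
    "",
    "Model comparisons (bootstrap p):",
    paste(vapply(names(result$comparisons), function(nm) {
      cc <- result$comparisons[[nm]]
      sprintf("  %s: target onset p = %.4g, scene onset p = %.4g", nm,
              cc$target_onset$p_boot, cc$scene_onset$p_boot)
    }, character(1)), collapse = "\n"))
  writeLines(report, file.path(out_dir, "report.md"))
  files <- setdiff(list.files(out_dir), "manifest.json")
  manifest <- as.list(md5sum(file.path(out_dir, files)))
  names(manifest) <- files
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE),
             file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
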