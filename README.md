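# choicephys

Behavioral and spike-train analysis of primate sequential accept/reject
choice tasks, with a first-class synthetic session generator.

## The problem

In the sequential choice task, a monkey views a scene, fixates a central
point, and is then shown one fractal object at a time at one of six
peripheral positions (15° eccentricity). A *good* object (associated with
liquid reward) is accepted by a saccade followed by ≥ 400 ms of fixation
inside the 8°-per-side target window; a *bad* (unrewarded) object is
rejected by staying at the center (*Stay*), saccading to it and returning
within 400 ms (*Return*), or looking elsewhere (*Other*). Return and Stay
are both *proactive* rejection — a goal-directed refusal of a choice. In
the companion fixation task the same objects flash beside the fixation
point and the monkey must suppress the reflexive saccade toward them —
*reactive* inhibition. Anterior striatal projection neurons (operationally,
units with baseline rates < 10 spikes/s) recorded during both tasks fall
into three response types, and the analysis asks which of them carry a
rejection signal that is proactive rather than reactive.

`choicephys` implements the full analysis chain for such experiments:

1. **behavior** — saccade detection (2D eye speed > 40°/s by central
   differences on 1 kHz samples, within 400 ms of target onset), gaze-action
   classification, Welch reaction-time tests, action-frequency tables, and
   Fisher/φ stay-proportion tests;
2. **spikes** — event-aligned PSTHs in 1-ms bins, spike-density functions
   (Gaussian kernel, σ = 20 ms), baseline Z-normalization
   (`z(t) = (r(t) − μ_base)/σ_base` over the 500 ms pre-event window), and
   the baseline-rate inclusion filter;
3. **cluster** — per-neuron features `(z_good_contra, z_bad_contra)` over
   the 100–300 ms post-target window, mean-silhouette selection of the
   cluster count, and canonical k-means labels (1 = good-preferring,
   2 = bad-preferring, 3 = remainder);
4. **mixedstats** — Gaussian linear mixed models
   `NeuronalActivity ~ Scene × Value × Direction + (1|monkey_ID) + (1|monkey_ID:Neuron_ID)`
   fitted by ML, compared against the intercept-only null by a parametric
   bootstrap on the deviance difference
   (`p = (1 + #{Δ* ≥ Δ_obs}) / (n_boot + 1)`), with Bonferroni-corrected
   post-hoc cell contrasts (α = 0.05/12 at target onset, 0.05/6 elsewhere);
5. **latency** — reaction-time quartile splits, Pearson correlation of
   quartile order with mean activity per neuron, and Wilcoxon signed-rank
   tests of the median correlation;
6. **pipeline** — end-to-end orchestration including the
   proactive-versus-reactive contrast (choice-task Return/Stay versus
   fixation-task object responses).

Because the in-vivo recordings are not publicly deposited, the `synth`
module generates complete sessions — trial schedules, behavioral policies
calibrated to the published reaction-time and action-count tables,
minimum-jerk eye traces, and inhomogeneous-Poisson spike trains from three
parametric response archetypes — so that every stage is testable end to
end.

## Worked example

```r
library(choicephys)

# Published action counts -> percentages (denominator: all bad-object trials)
bs <- summarize_actions(expand_action_counts(action_count_table()))
bs$action_counts[bs$action_counts$monkey == "C",
                 c("scene", "total", "Return", "Stay", "pct_Return", "pct_Stay")]
#>       scene total Return Stay pct_Return pct_Stay
#> 1         1  1479   1113  314       75.3     21.2
#> 2         2  1409   1100  284       78.1     20.2
#> 3         3  1396   1282   94       91.8      6.7
#> 4         4  1473   1253  167       85.1     11.3
#> 5 nonswitch  2888   2213  598       76.6     20.7
#> 6    switch  2869   2535  261       88.4      9.1

# A 45-neuron synthetic population, clustered by response type
task <- task_config(); pol <- behavior_policy("C")
sessions <- lapply(1:45, function(i) {
  arch <- neuron_archetype(c("cluster1_good", "cluster2_bad",
                             "cluster3_visual")[(i - 1) %% 3 + 1])
  simulate_choice_session(task, pol, arch, n_trials = 160, seed = i,
                          neuron_id = sprintf("n%02d", i),
                          components = "spikes")
})
features <- build_features(sessions)
round(select_k(features, k_range = 2:6, seed = 1)$silhouette_by_k, 3)
#>     2     3     4     5     6
#> 0.619 0.634 0.617 0.564 0.439          # silhouette peaks at k = 3
cl <- kmeans_assign(features, 3, seed = 2)
table(archetype = features$archetype, cluster = cl$labels)
#>                  cluster
#> archetype          1  2  3
#>   cluster1_good   15  0  0
#>   cluster2_bad     0 15  0
#>   cluster3_visual  1  0 14

# Rejection-type cluster: does target-onset activity depend on conditions?
tab <- activity_table(sessions[cl$labels == 2], "target_onset")
parametric_bootstrap_compare(tab, n_boot = 199, seed = 3)
#> <model_comparison> deviance null 1108.68 - full 679.09 = 429.59;
#>   p = 0.005 (199 boot, balanced engine)

# Good-preferring cluster: faster saccades on high-activity trials
latency_correlation_analysis(sessions[cl$labels == 1])$tests
#>     condition  n   median_r            p
#> 1  bad.contra 16 -0.2249176 3.225098e-01
#> 2    bad.ipsi 16 -0.3370749 8.325195e-02
#> 3 good.contra 16 -0.9748276 3.051758e-05   # negative latency coupling
#> 4   good.ipsi 16 -0.1109452 6.685486e-01
```

The percentage table reproduces the published per-scene Return/Stay
percentages exactly (rounding half-up to one decimal); the silhouette scan
recovers the three generating archetypes; the bootstrap p-value is at its
resolution floor (1/200) for the strongly condition-dependent
rejection-type cluster; and only the good-preferring cluster's
contralateral-good condition shows the negative latency–activity
correlation built into the generator.

The numbered scripts under `analysis/` run the same stages as a workflow
(`01_behavior_tables.R` → `06_reject_mode_contrast.R`), writing their
tables under `results/`.

## Scope

Real-data ingestion is limited to the documented session-bundle format
(`events.tsv`, `spikes.tsv`, `eye.tsv`, `meta.json`). Anatomical
reconstruction (MRI segmentation, recording-site mapping) and figure-level
reproduction of the published real-data tables are out of scope; the
mixed-model stage reproduces the *structure* and qualitative sign patterns
of those tables on synthetic data, not their numerical entries. See the
methods vignette (`vignettes/choicephys-methods.Rmd`) for the modeling
decisions and their rationale.
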