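Package: choicephys
Title: Behavioral and Spike-Train Analysis of Sequential Accept/Reject Choice Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing primate sequential accept/reject choice-task
    experiments with simultaneous eye tracking (1 kHz) and single-unit striatal
    recordings. Provides a synthetic session generator (task schedule, behavioral
    policy, minimum-jerk eye traces, inhomogeneous-Poisson spike trains from
    parametric response archetypes), velocity-threshold saccade detection and
    gaze-action classification, event-aligned PSTH and Gaussian spike-density
    estimation with baseline Z-normalization, silhouette-guided k-means
    classification of neuronal response types, Gaussian linear mixed-model
    inference with parametric-bootstrap model comparison and Bonferroni-corrected
    post-hoc contrasts, saccade-latency quartile correlation analysis, and an
    end-to-end pipeline contrasting proactive (choice rejection) and reactive
    (fixation) inhibition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    lmerTest,
    emmeans,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
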