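---
title: "Methods: models, parameters and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design decisions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette records the modeling choices behind `choicephys`: what the
synthetic generator emulates and what it deliberately does not, the
numerical conventions of each analysis stage, and the decisions taken
where the underlying experimental description left the design open.

## 1. What the synthetic generator emulates

The generator produces complete sessions for a sequential accept/reject
choice task and its companion fixation task. It is calibrated to the
published behavioral summaries and to the qualitative response taxonomy of
the recorded neurons; it is *not* a biophysical simulation.

### Task schedule

Each trial: a preparatory interval drawn uniformly from 1500–2000 ms, scene
onset, 1000 ms free viewing, fixation-point onset, 700 ms of required
fixation, then target onset. Targets appear at 15° eccentricity at one of
six angles (0°, 45°, 135°, 180°, 225°, 315°); every angle has a nonzero
horizontal component so contralateral/ipsilateral is always defined. The
acceptance window is a square of 8° per side and acceptance requires
400 ms of fixation inside it. Fixation-task trials present the two scene-1
objects alternately 2–4 times to one side of the fixation point (400 ms
on, 400 ms interstimulus interval) with reward 300 ms after the last
object.

### Behavioral policy

Reaction times are truncated normals on [80, 600] ms with per-(scene,
value) means and SDs taken from the published reaction-time table;
truncation prevents unphysical values while changing the printed means by
far less than their standard errors (the bounds sit ≥ 3.7 SDs from every
mean). Action probabilities for bad objects are the published per-scene
action counts normalized by the scene total; good objects are always
accepted (the recorded animals accepted good objects essentially always,
and no counts are published for them). Return trials hold the target for
100–300 ms before the return saccade, keeping the out-of-window dwell
below the 400 ms acceptance threshold. Fixation-break trials (choice task)
break during the fixation hold, before target onset.

### Eye traces

Saccades are minimum-jerk displacements, `s(τ) = 10τ³ − 15τ⁴ + 6τ⁵`, with
duration `20 ms + 1.5 ms/deg` of amplitude — enough to push peak speed far
above the 40°/s detection criterion for any ≥ 5° movement without fitting
a real main sequence. Because the minimum-jerk profile accelerates
smoothly, the first 1-ms central-difference sample exceeding 40°/s lags
the kinematic movement onset by ~2–3 ms for a 15° saccade; the generator
therefore time-shifts each movement so that the *detectable* onset
coincides with the commanded onset. This makes the round trip exact:
commanded onsets are recovered to within ±2 ms on noiseless traces, with
no tolerance hiding in the detector.

Fixational jitter is white noise low-passed with a Gaussian kernel
(σ = 25 ms) and rescaled to the requested position SD (default 0.05°).
The smoothing matters: white positional noise of realistic amplitude
aliases into hundreds of °/s of sample-to-sample velocity and would
swamp any velocity-threshold detector, whereas real fixational drift is
spectrally slow. With smoothed jitter the classifier still agrees with
the commanded actions at 0.3° noise.

Not emulated: main-sequence variability, microsaccades, blinks, pupil
size, calibration drift. Detection results on synthetic traces therefore
demonstrate correctness of the detector, not robustness to every
real-world artifact.

### Spike trains

Each neuron is an inhomogeneous Poisson process sampled by thinning
against a rate profile discretized at 1 kHz (matching the 1-ms PSTH
resolution downstream). The rate is a baseline (default 5 spikes/s, below
the 10 spikes/s projection-neuron criterion) plus, per object
presentation, a difference-of-exponentials kernel
(latency 90 ms, rise 20 ms, decay 80 ms, peak-normalized) scaled by a
(value × direction) amplitude matrix. The kernel timing places the
response peak inside the 100–300 ms analysis window. Three archetypes
encode the response taxonomy the analysis is designed to recover:

| archetype | good contra/ipsi | bad contra/ipsi | extras |
|---|---|---|---|
| `cluster1_good` | 35 / 20 | 7 / 6 | latency coupling −0.5 on good-contra |
| `cluster2_bad` | 7 / 7 | 33 / 32 | — |
| `cluster3_visual` | 30 / 28 | 30 / 28 | sustained bad component (amp 5, decay 300 ms) |

Amplitudes are in spikes/s at the kernel peak. They were chosen once so
that the three archetypes occupy distinct regions of the
`(z_good_contra, z_bad_contra)` feature plane — good-preferring,
bad-preferring, and strong-but-value-agnostic — with separations a few
times the feature sampling noise; the archetype *ordering* constraints
(good > bad for type 1, bad > good with contra ≈ ipsi for type 2, early
value-agnostic transient for type 3) are validated at construction.
A per-neuron log-normal gain (SD 0.1) adds across-neuron amplitude
heterogeneity within each archetype. During the fixation task all
response amplitudes are multiplied by `fixation_attenuation`
(default 0.3), implementing the reduced engagement of these neurons
under reactive-inhibition demands; setting it to 1 is the negative
control in which the choice-versus-fixation contrast must vanish.

The latency coupling multiplies the response amplitude by
`max(0, 1 − 0.5 · z(RT))` on contralateral good trials, producing the
negative latency–activity correlation in the good-preferring archetype
only.

### Contralateral convention

The recording hemisphere is stored in session metadata (default left) and
"contra" means the target's x-coordinate sign is opposite that
hemisphere. The experimental description does not state its convention;
any fixed convention suffices for synthetic data, and the choice only
relabels `Direction`.

## 2. Analysis conventions

* All windows are half-open `[start, end)` in ms relative to the aligning
  event at 0; a spike exactly at the event falls in bin `[0, 1)`. This
  removes double-counting ambiguity at bin edges.
* The spike-density kernel is truncated at ±4σ and renormalized, so the
  impulse-response area is conserved to < 0.1%.
* Baselines: Z-normalization uses the 500 ms immediately before the
  aligning event; the inclusion filter uses 1500–500 ms before scene
  onset and applies a strict `< 10 spikes/s` criterion (a neuron at
  exactly 10 spikes/s is excluded).
* Neurons whose baseline SD is zero (e.g. silent units) are flagged
  degenerate and excluded from population maps rather than
  epsilon-padded; padding would fabricate Z-scores with no information.
* Population averages weight neurons equally, not by trial count.
* Saccade-aligned and early-target window presets
  (`saccade_peri = [−150, 50)`, `target_early = [50, 200)`) are exposed
  alongside the primary 100–300 ms windows; the 100–300 ms values are the
  defaults everywhere.
* Action classification searches the full 1000-ms decision window (the
  interval after which the fixation point reappears on rejection trials),
  while *reaction-time* detection keeps the stricter 400-ms criterion.
  A return saccade launched at 410 ms is still behaviorally a Return,
  but contributes no RT to the latency analyses. The central "stay" zone
  radius is 4°, half the target window side, as no radius is stated.

## 3. Clustering

Features are per-neuron trial-mean Z activities for contralateral good
and bad objects, 100–300 ms post target, standardized against the
neuron's own pre-target baseline (consistent with the PSTH Z-procedure;
whether the original analysis standardized across neurons instead is not
stated). k-means uses k-means++ initialization with 50 restarts under a
fixed seed and per-iteration assertion that the objective never
increases; labels are canonicalized by centroid geometry on the
`z_good − z_bad` axis so that cluster 1 is always the most
good-preferring and cluster 2 the most bad-preferring centroid. The
cluster count is selected by mean silhouette over k = 2..8 — scanning,
rather than presetting K = 3, turns the expected three-type taxonomy into
a testable outcome; exact silhouette ties resolve to the smallest k.

## 4. Mixed models and the parametric bootstrap

The response is a continuous cell-mean Z activity, so the "generalized"
linear mixed model is read as a Gaussian LMM with identity link. Models
are fitted by ML, not REML, because the bootstrap compares deviances
across different fixed-effect structures (REML deviances are available
via `fit_lmm(..., reml = TRUE)` for variance reporting). Random effects
are nested intercepts, monkey and monkey:neuron, following the printed
model formulas; an experimental-session intercept appears in the
surrounding prose but not in the formulas, and the formulas are taken as
authoritative. The bootstrap simulates from the fitted null (new
random-effect and residual draws), refits both models per replicate, and
uses the `(1 + x)/(n + 1)` p-value estimator so p is never exactly zero.

### The balanced closed-form engine

The designs this pipeline produces are exactly balanced: every neuron
contributes one row per condition cell, and the two monkeys carry equal
neuron counts. In that case the data space splits into three orthogonal
strata — within-neuron contrasts, neuron means within monkeys, and monkey
means — that are isotropic Gaussian with variances
σ²ₑ, σ²ₑ + qσ²_b, and σ²ₑ + qσ²_b + Jqσ²_a (q cells per neuron, J neurons
per monkey). Full-factorial fixed effects live entirely in the
within-neuron stratum plus the grand mean, so GLS equals cell means and
the profiled ML deviance is a sum of independent stratum terms
`D_k log λ_k + S_k/λ_k` under the monotonicity constraint
λ₁ ≤ λ₂ ≤ λ₃, solved exactly by pool-adjacent-violators (pooling is the
boundary case of a zero variance component). This is an exact ML
solution, not an approximation; the test suite asserts agreement with
`lme4` deviances to 1e-6 on balanced datasets, including
boundary-singular ones, and the engine falls back to `lme4::refit()`
whenever a design does not qualify. The closed form is what makes a
500-simulation × 199-replicate null calibration of the bootstrap
practical in the test suite.

With two monkeys the monkey-level stratum has a single informative
contrast, so the monkey variance component is estimable but extremely
noisy (and ML shrinks it by the factor (M−1)/M). The test suite
therefore checks point recovery of the neuron and residual components at
the study's 2-monkey scale and of the monkey component in a wider
12-monkey design; no single-dataset accuracy claim is made for a
variance estimated from one degree of freedom.

### Post-hoc contrasts

Cell means and pairwise t contrasts come from `emmeans` with Satterthwaite
degrees of freedom (the df method is not stated in the source analysis;
Satterthwaite is the `lmerTest` convention and residual df is available
by refitting). Bonferroni families follow the stated α levels: m = 12 at
target onset (six good-versus-bad tests plus six across-scene tests —
the across-scene family is inferred from prose, as its pairs are not
enumerated), m = 6 for saccade-aligned and choice-versus-fixation
analyses. `p_adj = min(1, m·p_raw)` is applied against the stated m even
when fewer contrasts are tabulated. Effect sizes are mean differences
scaled by the model residual SD.

## 5. Latency analysis

Trials with a detected reaction time are sorted (stable in input order),
split into four contiguous groups with any remainder going to the
earliest groups (9 trials → sizes 3, 2, 2, 2; the rule is unspecified in
the source, and a fixed rule makes results deterministic), and the
Pearson correlation of group order (1–4) with group-mean activity is the
per-neuron statistic — the minimal reading of "correlation between group
order and mean activity". Medians are tested per condition (matching the
per-condition panel structure of the source figures) with the exact
signed-rank distribution for n ≤ 25 without ties and the normal
approximation otherwise.

## 6. The proactive-versus-reactive contrast

Scene-1 bad-object trials only (object values are constant there), four
cells per neuron and side: choice-Return, choice-Stay, fixation-good,
fixation-bad, all as Z activity 100–300 ms post object onset. A
parametric-bootstrap model comparison gates an m = 6 post-hoc family. Two
qualitative flags are derived from the post-hoc table only:
`return_vs_stay_ns` (the rejection signal does not depend on whether a
saccade occurred) and `choice_gt_fixation`, which compares *value-matched*
cells — choice-task bad objects versus fixation-task bad objects — so
that the flag isolates the task effect rather than the value preference
(a bad-preferring neuron responds weakly to fixation-task good objects
whatever the attenuation, so good-fixation cells cannot serve as the
negative control). Populations with fewer than 10 complete neurons
report cell means but skip the population test.

## 7. Stay-proportion test construction

The 2×2 table for the stay-proportion comparison (value-stable scenes 1–2
versus value-swapped scenes 3–4) is not fully specified in the source.
Both constructions are implemented: Stay-versus-Return (primary) and
Stay-versus-all-other-outcomes. Computed on the printed counts, the
primary construction reproduces the published φ values for both monkeys
(0.17 and 0.07 after rounding) and yields Fisher p-values matching the
published bounds, so it is the default; the alternative remains available
via `stay_table(..., "stay-vs-all")`.

## 8. Problem sizes in the test suite

The suite exercises the statistical machinery at sizes chosen to make
sampling envelopes meaningful while keeping a desk-scale run: cluster
recovery uses 150 neurons (50 per archetype) with 160–320 trials per
session across 10 seeds; bootstrap calibration uses 500 simulated null
tables (2 monkeys × 60 neurons × 16 cells) with 199 replicates each, with
the rejection rate required to fall inside the 95% binomial envelope
around 0.05; the qualitative-pattern suite uses a 42-neuron mixed
population plus fixation sessions. Pipeline-level tests use reduced
populations (6–12 neurons per archetype) where only determinism or
degradation behavior is at stake. `n_boot = 10000` — the inferential
setting for real analyses — is available through `pipeline_config()`.

## 9. Known limitations

* The generator's archetypes are stylized: real striatal populations mix
  response types continuously, and cluster boundaries on real data will
  be softer than on synthetic data. Passing recovery tests demonstrates
  the pipeline's correctness, not that real data would cluster as
  cleanly.
* Sessions are stationary: no learning, adaptation, or electrode drift.
* The monkey-level variance component is intrinsically ill-determined
  with two monkeys (one informative contrast); inference about fixed
  effects is unaffected, which is why the bootstrap calibration holds.
* The balanced engine requires exact balance; dropped cells silently
  route comparisons through the slower `lme4` path.
* Eye traces are kinematically idealized; the 40°/s detector has not
  been stress-tested against real oculomotor artifacts.
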