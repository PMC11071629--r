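# Shared builders for the test suite. Everything is generated in code;
# no binary fixtures.

fix_task <- task_config()

fix_policy_C <- behavior_policy("C")
fix_policy_S <- behavior_policy("S")

# A degenerate policy: good objects always accepted, bad always returned.
degenerate_policy <- function() {
  pol <- behavior_policy("C")
  pol$p_Accept <- ifelse(pol$value == "good", 1, 0)
  pol$p_Return <- ifelse(pol$value == "bad", 1, 0)
  pol$p_Stay <- 0; pol$p_Other <- 0; pol$p_FixBreak <- 0
  pol
}

# Quick spikes-only choice session.
quick_session <- function(arch_label, seed, n_trials = 160, monkey = "C",
                          neuron_id = sprintf("n%04d", seed %% 10000)) {
  pol <- if (monkey == "C") fix_policy_C else fix_policy_S
  simulate_choice_session(fix_task, pol, neuron_archetype(arch_label),
                          n_trials = n_trials, seed = seed,
                          monkey_id = monkey, neuron_id = neuron_id,
                          components = "spikes")
}

# Hand-built session around an explicit spike train (for filter tests).
manual_session <- function(spikes, n_scenes = 20, spacing = 5000) {
  t_scene <- 2000 + spacing * seq_len(n_scenes)
  trials <- data.frame(
    trial_id = seq_len(n_scenes), scene = 1L, value = "bad",
    direction = "contra", angle_deg = 0, t_scene_ms = t_scene,
    t_fp_ms = t_scene + 1000, t_target_ms = t_scene + 1700,
    t_saccade_go_ms = NA_real_, t_saccade_back_ms = NA_real_,
    action = factor("Stay", levels = c("Accept", "Return", "Stay",
                                       "Other", "FixBreak")),
    rt_ms = NA_real_, reward = FALSE, t_end_ms = t_scene + 3200)
  structure(list(monkey_id = "C", neuron_id = "manual", region = "Cd",
                 hemisphere = "left", task = "choice", seed = 0,
                 config = fix_task, trials = trials, spikes = spikes,
                 eye = NULL),
            class = "ephys_session")
}

# ---- independent oracles ------------------------------------------------

# Textbook Welch statistic.
oracle_welch <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Two-sided Fisher exact p by complete enumeration over the hypergeometric
# support of a 2x2 table with fixed margins.
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- vapply(support, function(k) {
    exp(lchoose(r1, k) + lchoose(r2, c1 - k) - lchoose(n, c1))
  }, numeric(1))
  p_obs <- probs[support == a]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

oracle_phi <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  (a * d - b * c) / sqrt((a + b) * (c + d) * (a + c) * (b + d))
}

# Exact two-sided signed-rank p by enumeration of all 2^n sign patterns
# (assumes no ties among |x| and no zeros).
oracle_signed_rank_p <- function(x) {
  n <- length(x)
  ranks <- rank(abs(x))
  v_obs <- sum(ranks[x > 0])
  vs <- vapply(0:(2^n - 1), function(mask) {
    signs <- bitwAnd(bitwShiftR(mask, 0:(n - 1)), 1L) == 1L
    sum(ranks[signs])
  }, numeric(1))
  mu <- n * (n + 1) / 4
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

oracle_pearson <- function(x, y) {
  xm <- x - mean(x); ym <- y - mean(y)
  sum(xm * ym) / sqrt(sum(xm^2) * sum(ym^2))
}
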