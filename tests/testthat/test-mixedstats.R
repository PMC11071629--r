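test_that("closed-form balanced ML matches lme4 deviances", {
  for (sc in 1:5) {
    tab <- simulate_activity_table(
      2, 10, cell_means = if (sc %% 2) 0 else rnorm(16, 0, 1),
      sd_monkey = c(0, 0.5, 1)[sc %% 3 + 1], seed = 100 + sc)
    lay <- choicephys:::balanced_layout(tab)
    expect_false(is.null(lay))
    bf <- choicephys:::balanced_ml_fit(tab$NeuronalActivity, lay, TRUE)
    bn <- choicephys:::balanced_ml_fit(tab$NeuronalActivity, lay, FALSE)
    expect_equal(bf$deviance,
                 fit_lmm(tab, ~ Scene * Value * Direction)$deviance,
                 tolerance = 1e-6)
    expect_equal(bn$deviance, fit_lmm(tab, ~ 1)$deviance,
                 tolerance = 1e-6)
    # nesting: the null can never fit better
    expect_gte(bn$deviance, bf$deviance - 1e-6)
  }
})

test_that("the balanced engine declines unbalanced designs", {
  tab <- simulate_activity_table(2, 10, seed = 7)
  tab <- tab[-3, ]   # remove one cell
  expect_null(choicephys:::balanced_layout(tab))
  expect_error(parametric_bootstrap_compare(tab, n_boot = 19,
                                            engine = "balanced"),
               "does not qualify")
})

test_that("degenerate-limit fit recovers the grand mean", {
  tab <- simulate_activity_table(2, 15, cell_means = 2, sd_monkey = 0,
                                 sd_neuron = 0, sd_resid = 1, seed = 8)
  fit <- fit_lmm(tab, ~ 1)
  est <- lme4::fixef(fit$model)[["(Intercept)"]]
  expect_lt(abs(est - 2), 3 / sqrt(nrow(tab)))
  expect_true(fit$singular)   # zero variance components hit the boundary
})

test_that("variance components are recovered from generated data", {
  # neuron and residual SDs at the study scale
  tab <- simulate_activity_table(2, 60, sd_monkey = 0.5, sd_neuron = 1,
                                 sd_resid = 1, seed = 9)
  fit <- fit_lmm(tab, ~ 1)
  s2 <- fit$sigma2
  expect_lt(abs(sqrt(s2[["monkey_ID:Neuron_ID"]]) - 1), 0.25)
  expect_lt(abs(sqrt(s2[["Residual"]]) - 1), 0.25)
  # the monkey component has a single informative contrast at M = 2, so
  # point recovery needs a wider design
  tab12 <- simulate_activity_table(12, 20, sd_monkey = 0.5, sd_neuron = 1,
                                   sd_resid = 1, seed = 10)
  fit12 <- fit_lmm(tab12, ~ 1)
  expect_lt(abs(sqrt(fit12$sigma2[["monkey_ID"]]) - 0.5), 0.25)
})

test_that("bootstrap comparison behaves at the extremes", {
  tab <- simulate_activity_table(2, 12, seed = 11)
  same <- parametric_bootstrap_compare(tab, full = ~ 1, null = ~ 1,
                                       n_boot = 49, seed = 1)
  expect_equal(same$observed_diff, 0)
  expect_equal(same$p_boot, 1)
  strong <- simulate_activity_table(
    2, 30, cell_means = rep(c(0, 2), each = 8), seed = 12)
  res <- parametric_bootstrap_compare(strong, n_boot = 199, seed = 2)
  expect_lte(res$p_boot, 0.01)
  expect_gte(res$observed_diff, 0)
  expect_error(parametric_bootstrap_compare(tab, n_boot = 5), "at least 19")
})

test_that("bootstrap p is invariant to affine rescaling of activity", {
  tab <- simulate_activity_table(2, 20, cell_means = rnorm(16, 0, 0.3),
                                 seed = 13)
  p0 <- parametric_bootstrap_compare(tab, n_boot = 99, seed = 5)$p_boot
  tab2 <- tab
  tab2$NeuronalActivity <- tab2$NeuronalActivity * 10 + 5
  p1 <- parametric_bootstrap_compare(tab2, n_boot = 99, seed = 5)$p_boot
  expect_equal(p0, p1)
})

test_that("lme4 engine agrees with the balanced engine in distribution", {
  tab <- simulate_activity_table(2, 10, cell_means = rep(c(0, 0.7),
                                                         each = 8),
                                 seed = 14)
  pb <- parametric_bootstrap_compare(tab, n_boot = 99, seed = 3,
                                     engine = "balanced")
  pl <- parametric_bootstrap_compare(tab, n_boot = 99, seed = 3,
                                     engine = "lme4")
  expect_equal(pb$observed_diff, pl$observed_diff, tolerance = 1e-4)
  expect_equal(pb$deviance_full, pl$deviance_full, tolerance = 1e-5)
  expect_lt(abs(pb$p_boot - pl$p_boot), 0.12)
  expect_equal(pl$engine, "lme4")
})

test_that("power rises with effect size and type-I error is controlled", {
  cells <- rep(c(0, 1), each = 8)
  pvals <- vapply(c(0, 0.5, 2), function(es) {
    tab <- simulate_activity_table(2, 30, cell_means = cells * es,
                                   seed = 15)
    parametric_bootstrap_compare(tab, n_boot = 199, seed = 6)$p_boot
  }, numeric(1))
  expect_true(all(diff(pvals) <= 0))
  expect_gt(pvals[1], 0.05)
  expect_lte(pvals[3], 0.005)
})

test_that("post-hoc contrasts report calibrated cell comparisons", {
  truth <- expand.grid(Scene = 1:4, Value = c("good", "bad"),
                       Direction = c("contra", "ipsi"))
  mu <- ifelse(truth$Value == "bad", 2, 0)
  tab <- simulate_activity_table(2, 25, cell_means = mu, seed = 16)
  fit <- fit_lmm(tab, ~ Scene * Value * Direction)
  ph <- posthoc_pairwise(fit, ~ Value * Direction | Scene, m = 12)
  bg <- ph[grepl("bad contra - good contra", ph$contrast), ]
  expect_equal(nrow(bg), 4)
  expect_true(all(bg$significant))
  expect_true(all(bg$t > 0))
  # Bonferroni arithmetic
  expect_equal(ph$p_adj, pmin(1, 12 * ph$p_raw))
  # cell means recovered
  expect_lt(abs(mean(bg$mean_1 - bg$mean_2) - 2), 0.3)
  null_ph <- ph[grepl("bad contra - bad ipsi", ph$contrast), ]
  expect_true(all(!null_ph$significant))
})

test_that("with random variances forced to zero the t statistics match OLS", {
  truth <- expand.grid(Scene = 1:4, Value = c("good", "bad"),
                       Direction = c("contra", "ipsi"))
  tab <- simulate_activity_table(2, 20,
                                 cell_means = ifelse(truth$Value == "bad",
                                                     1, 0),
                                 sd_monkey = 0, sd_neuron = 0,
                                 sd_resid = 1, seed = 17)
  # force the neuron and monkey strata to zero exactly by centring each
  # neuron's residual mean, so the mixed fit hits the variance boundary
  resid <- tab$NeuronalActivity -
    ave(tab$NeuronalActivity, tab$Value, FUN = mean)
  tab$NeuronalActivity <- tab$NeuronalActivity -
    ave(resid, tab$Neuron_ID, FUN = mean)
  fit <- fit_lmm(tab, ~ Value, reml = TRUE)
  expect_true(fit$singular)
  # the exact-boundary fit triggers a harmless rank warning in emmeans
  ph <- suppressWarnings(posthoc_pairwise(fit, ~ Value, m = 1))
  ols <- lm(NeuronalActivity ~ Value, data = tab)
  em_ols <- emmeans::emmeans(ols, ~ Value)
  t_ols <- as.data.frame(emmeans::contrast(em_ols, "pairwise"))$t.ratio
  expect_equal(ph$t, t_ols, tolerance = 1e-6)
})
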