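test_that("binning uses half-open 1-ms bins aligned at the event", {
  p <- align_and_bin(c(100), event_times = 100, window = c(-5, 5))
  expect_equal(sum(p$counts), 1)
  expect_equal(p$counts[1, which(p$bins == 0)], 1L)
  # spike just before the event falls in bin [-1, 0)
  p2 <- align_and_bin(c(99.999), event_times = 100, window = c(-5, 5))
  expect_equal(p2$counts[1, which(p2$bins == -1)], 1L)
  expect_true(all(align_and_bin(numeric(0), 0, c(-5, 5))$counts == 0))
  expect_error(align_and_bin(1:3, numeric(0)), "non-empty")
  expect_error(align_and_bin(1:3, 0, c(5, -5)), "pre < post")
})

test_that("binned counts conserve the spikes in every trial window", {
  set.seed(1)
  spikes <- sort(runif(2000, 0, 100000))
  events <- seq(5000, 95000, by = 1000)
  win <- c(-400, 400)
  p <- align_and_bin(spikes, events, win)
  for (i in seq_along(events)) {
    expect_equal(sum(p$counts[i, ]),
                 sum(spikes >= events[i] + win[1] &
                       spikes < events[i] + win[2]))
  }
  # mean per-bin count of a 10 spikes/s train is ~0.010
  lam <- 10 / 1000
  mb <- mean(p$counts)
  expect_lt(abs(mb - 2000 / 100000),
            3 * sqrt(lam / (length(events) * ncol(p$counts))))
})

test_that("Gaussian smoothing preserves area and is shift-equivariant", {
  p <- align_and_bin(c(500), 500, c(-200, 200))
  sdf <- smooth_sdf(p, sigma = 20)
  expect_equal(sum(sdf) / 1000, 1, tolerance = 1e-3)   # unit impulse area
  # shifted impulse gives a shifted response
  p2 <- align_and_bin(c(530), 500, c(-200, 200))
  sdf2 <- smooth_sdf(p2, sigma = 20)
  expect_equal(sdf[50:250], sdf2[80:280], tolerance = 1e-12)
  # near-zero sigma returns the raw histogram scale
  sdf0 <- smooth_sdf(p, sigma = 0.2)
  expect_equal(which.max(sdf0), which(p$bins == 0))
  expect_gt(max(sdf0), 990)
  expect_error(smooth_sdf(p, sigma = 0), "positive")
})

test_that("constant-rate input smooths to the same constant", {
  # exactly constant trial-averaged PSTH at 5 spikes/s: one spike per bin
  # across every 200 trials
  nb <- 1000; nt <- 200
  counts <- matrix(0L, nt, nb)
  counts[cbind((seq_len(nb) - 1L) %% nt + 1L, seq_len(nb))] <- 1L
  p <- structure(list(counts = counts, bins = seq(-500, 499),
                      window = c(-500, 500)), class = "aligned_psth")
  sdf <- smooth_sdf(p, sigma = 20)
  interior <- sdf[100:900]
  expect_true(all(abs(interior - 5) < 1e-9))
})

test_that("baseline statistics are Poisson-calibrated and flag degeneracy", {
  set.seed(3)
  events <- seq(2000, 400000, by = 2000)
  spikes <- sort(runif(round(8 / 1000 * 401000), 0, 401000))
  b <- baseline_stats(spikes, events, "pre_event_500")
  se <- b$sd / sqrt(length(events))
  expect_lt(abs(b$mean - 8), 3 * se)
  empty <- baseline_stats(numeric(0), events, "pre_event_500")
  expect_equal(empty$mean, 0)
  expect_true(empty$degenerate)
})

test_that("Z-scoring maps baseline-level activity to zero", {
  base <- list(mean = 4, sd = 2)
  flat <- structure(rep(4, 100), bins = 0:99)
  z <- zscore_sdf(flat, base)
  expect_true(all(z$rate_z == 0))
  z2 <- zscore_sdf(structure(rep(8, 100), bins = 0:99), base)
  expect_true(all(z2$rate_z == 2))
  expect_error(zscore_sdf(flat, list(mean = 0, sd = 0)), "degenerate")
  flagged <- zscore_sdf(flat, list(mean = 0, sd = 0),
                        allow_degenerate = TRUE)
  expect_true(flagged$degenerate)
})

test_that("Z-scored baseline window is centred for stationary input", {
  set.seed(4)
  events <- seq(2000, 2000 + 500 * 1600, by = 1600)[1:500]
  t_end <- max(events) + 1000
  spikes <- sort(runif(rpois(1, 6 / 1000 * t_end), 0, t_end))
  nsdf <- session_sdf(manual_session(spikes), events,
                      window = c(-500, 500))
  base_bins <- nsdf$bins >= -500 & nsdf$bins < 0
  expect_lt(abs(mean(nsdf$rate_z[base_bins])), 0.05)
})

test_that("window means follow the discrete summation oracle", {
  const <- structure(rep(3.5, 400), bins = 0:399)
  expect_equal(window_mean(const, c(100, 300)), 3.5)
  ramp <- structure(seq(0, 1, length.out = 200), bins = 0:199)
  expect_equal(window_mean(ramp, c(0, 200)),
               mean(seq(0, 1, length.out = 200)), tolerance = 1e-12)
  delta <- structure(c(rep(0, 50), 1000, rep(0, 349)), bins = 0:399)
  expect_equal(window_mean(delta, c(100, 300)), 0)
  expect_error(window_mean(const, c(500, 600)), "overlap")
})

test_that("inclusion filter applies the strict 10 spikes/s criterion", {
  s5 <- manual_session(sort(runif(5 * 120, 0, 120000)))
  expect_true(inclusion_filter(s5))
  s12 <- manual_session(sort(runif(12 * 120, 0, 120000)))
  expect_false(inclusion_filter(s12))
  # exactly 10 spikes/s in every baseline window: excluded (strict <)
  regular <- seq(0.5, 120000, by = 100)   # 10 Hz everywhere
  expect_false(inclusion_filter(manual_session(regular)))
  expect_true(inclusion_filter(manual_session(seq(0.5, 120000, by = 101))))
})

test_that("activity tables are deterministic and carry the cell structure", {
  s <- quick_session("cluster2_bad", seed = 51, n_trials = 160)
  t1 <- activity_table(list(s), "target_onset")
  t2 <- activity_table(list(s), "target_onset")
  expect_identical(t1, t2)
  expect_setequal(levels(t1$Value), c("good", "bad"))
  expect_setequal(levels(t1$Direction), c("contra", "ipsi"))
  expect_true(all(t1$n_trials >= 1))
  # bad-preferring neuron: bad cells above good cells on average
  expect_gt(mean(t1$NeuronalActivity[t1$Value == "bad"]),
            mean(t1$NeuronalActivity[t1$Value == "good"]))
})
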