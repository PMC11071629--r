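blob_features <- function(centers, n_each = 50, sd = 0.1, seed = 1) {
  set.seed(seed)
  do.call(rbind, lapply(seq_len(nrow(centers)), function(i) {
    cbind(rnorm(n_each, centers[i, 1], sd),
          rnorm(n_each, centers[i, 2], sd))
  }))
}

test_that("silhouette selection recovers the generating blob count", {
  three <- blob_features(rbind(c(0, 0), c(4, 0), c(0, 4)), sd = 0.1,
                         seed = 2)
  sel3 <- select_k(three, k_range = 2:6, seed = 1)
  expect_equal(sel3$k_best, 3)
  two <- blob_features(rbind(c(0, 0), c(5, 5)), sd = 0.1, seed = 3)
  sel2 <- select_k(two, k_range = 2:6, seed = 1)
  expect_equal(sel2$k_best, 2)
  # silhouettes agree with the reference implementation
  res <- sel3$results[["3"]]
  ref <- cluster::silhouette(res$labels, dist(three))
  expect_equal(res$silhouette, mean(ref[, "sil_width"]),
               tolerance = 1e-10)
})

test_that("k-means is deterministic, canonical and matches stats::kmeans", {
  x <- blob_features(rbind(c(5, 1), c(1, 5), c(4.5, 4.5)), sd = 0.3,
                     seed = 4)
  r1 <- kmeans_assign(x, 3, seed = 7)
  r2 <- kmeans_assign(x, 3, seed = 7)
  expect_identical(r1$labels, r2$labels)
  # canonical numbering: cluster 1 most good-preferring, cluster 2 most
  # bad-preferring
  d <- r1$centroids[, 1] - r1$centroids[, 2]
  expect_equal(which.max(d), c(cluster1 = 1L))
  expect_equal(which.min(d), c(cluster2 = 2L))
  # objective matches an independent k-means on well-separated data
  ref <- kmeans(x, 3, nstart = 25)
  expect_equal(r1$wss, ref$tot.withinss, tolerance = 1e-8)
  expect_error(kmeans_assign(x, 1), "at least 2")
  expect_error(kmeans_assign(x[1:2, ], 3), "exceeds")
})

test_that("assignment is invariant to duplication and permutation", {
  x <- blob_features(rbind(c(0, 0), c(4, 0), c(0, 4)), n_each = 20,
                     sd = 0.2, seed = 5)
  base <- kmeans_assign(x, 3, seed = 11)
  dup <- kmeans_assign(rbind(x, x), 3, seed = 11)
  expect_equal(dup$centroids, base$centroids, tolerance = 1e-8)
  perm <- sample(nrow(x))
  shuf <- kmeans_assign(x[perm, ], 3, seed = 11)
  expect_equal(shuf$labels, base$labels[perm])
})

test_that("accuracy degrades gracefully as separation shrinks", {
  centers <- rbind(c(5, 1), c(1, 4.7), c(4.3, 4.9))
  acc <- vapply(c(0.5, 1, 2), function(scale) {
    x <- blob_features(centers * scale, n_each = 40, sd = 0.6, seed = 6)
    truth <- rep(1:3, each = 40)
    label_accuracy(kmeans_assign(x, 3, seed = 13)$labels, truth)
  }, numeric(1))
  expect_gt(acc[1], 0.8)
  expect_true(all(diff(acc) >= -0.02))   # monotone up to noise
  expect_gte(acc[3], 0.99)
})

test_that("features from spiking sessions separate the archetypes", {
  labels <- rep(c("cluster1_good", "cluster2_bad", "cluster3_visual"),
                each = 8)
  sessions <- lapply(seq_along(labels), function(i) {
    quick_session(labels[i], seed = 600 + i,
                  neuron_id = sprintf("n%03d", i))
  })
  f <- build_features(sessions)
  expect_equal(nrow(f), length(labels))
  by_arch <- split(f, f$archetype)
  expect_gt(mean(by_arch$cluster1_good$z_good_contra),
            mean(by_arch$cluster1_good$z_bad_contra))
  expect_gt(mean(by_arch$cluster2_bad$z_bad_contra),
            mean(by_arch$cluster2_bad$z_good_contra))
  cl <- kmeans_assign(f, 3, seed = 17)
  expect_gte(label_accuracy(cl$labels, f$archetype), 0.9)
})

test_that("feature construction drops under-sampled neurons", {
  s <- quick_session("cluster1_good", seed = 71, n_trials = 12)
  expect_message(
    expect_error(build_features(list(s), min_trials = 10), "no usable"),
    "too few")
})
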