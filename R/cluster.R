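#' Two-dimensional response features per neuron
#'
#' For each session (neuron), the Z-scored mean window activity in response
#' to contralateral good and contralateral bad objects, computed over the
#' 100-300 ms post-target window against the neuron's own 500-ms pre-target
#' baseline. Neurons lacking the minimum trial count in either condition,
#' or with a degenerate baseline, are dropped with a message.
#'
#' @param sessions List of `ephys_session`s (choice task).
#' @param window Analysis window, ms post target onset.
#' @param min_trials Minimum good-contra and bad-contra trial counts.
#' @return Data frame with `neuron_id`, `z_good_contra`, `z_bad_contra`.
#' @export
build_features <- function(sessions, window = c(100, 300), min_trials = 5) {
  rows <- list()
  for (s in sessions) {
    tr <- s$trials
    keep <- !is.na(tr$t_target_ms) & tr$direction == "contra"
    good <- keep & tr$value == "good"
    bad <- keep & tr$value == "bad"
    if (sum(good) < min_trials || sum(bad) < min_trials) {
      message("neuron ", s$neuron_id, ": too few contralateral trials, dropped")
      next
    }
    ev <- tr$t_target_ms[keep]
    act <- trial_window_activity(s$spikes, ev, window = window)
    if (act$baseline$degenerate) {
      message("neuron ", s$neuron_id, ": degenerate baseline, dropped")
      next
    }
    val <- tr$value[keep]
    rows[[length(rows) + 1L]] <- data.frame(
      neuron_id = paste(s$monkey_id, s$neuron_id, sep = "_"),
      z_good_contra = mean(act$z[val == "good"]),
      z_bad_contra = mean(act$z[val == "bad"]),
      archetype = if (is.null(s$archetype)) NA_character_ else s$archetype,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) stop("no usable neurons")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  as.matrix(features[, c("z_good_contra", "z_bad_contra")])
}

kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1)) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[j + 1, ] <- x[sample.int(n, 1, prob = probs), ]
    nd <- rowSums((x - matrix(centers[j + 1, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, nd)
  }
  centers
}

lloyd_once <- function(x, k, max_iter = 100) {
  n <- nrow(x)
  xsq <- rowSums(x^2)
  dist2 <- function(centers) {
    # squared Euclidean distances, n x k
    d <- xsq - 2 * x %*% t(centers) +
      matrix(rowSums(centers^2), n, k, byrow = TRUE)
    pmax(d, 0)
  }
  centers <- kmeanspp_init(x, k)
  d <- dist2(centers)
  lab <- max.col(-d, ties.method = "first")
  wss <- Inf
  for (iter in seq_len(max_iter)) {
    for (j in seq_len(k)) {
      sel <- lab == j
      if (any(sel)) {
        centers[j, ] <- colMeans(x[sel, , drop = FALSE])
      } else {
        # re-seed an empty cluster at the worst-fit point
        centers[j, ] <- x[which.max(d[cbind(seq_len(n), lab)]), ]
      }
    }
    d <- dist2(centers)
    lab <- max.col(-d, ties.method = "first")
    new_wss <- sum(d[cbind(seq_len(n), lab)])
    # Lloyd iterations never increase the objective
    stopifnot(new_wss <= wss + 1e-8)
    if (abs(wss - new_wss) < 1e-12) break
    wss <- new_wss
  }
  list(labels = lab, centers = centers, wss = new_wss)
}

#' k-means classification of response features
#'
#' Lloyd's algorithm with k-means++ initialization and multiple restarts
#' (best within-cluster sum of squares wins), deterministic under a fixed
#' seed. Cluster labels are canonicalized by centroid geometry on the
#' `z_good_contra - z_bad_contra` axis: the most good-preferring centroid
#' becomes cluster 1, the most bad-preferring cluster 2, and (for k = 3)
#' the remainder cluster 3; for other k the remaining clusters follow in
#' descending order of the difference.
#'
#' @param features Feature data frame from [build_features()], or a
#'   numeric matrix (first column treated as the good response, second as
#'   the bad response).
#' @param k Number of clusters (>= 2, <= number of points).
#' @param seed Integer seed.
#' @param n_restarts Number of k-means++ restarts.
#' @return A `cluster_result`: list with `k`, `labels` (canonical, in
#'   `1..k`), `centroids`, `wss`, `silhouette` (mean silhouette width),
#'   `seed`.
#' @export
kmeans_assign <- function(features, k = 3, seed = 1, n_restarts = 50) {
  x <- feature_matrix(features)
  if (k < 2) stop("k must be at least 2")
  if (k > nrow(x)) stop("k exceeds the number of points")
  set.seed(seed)
  best <- NULL
  for (r in seq_len(n_restarts)) {
    fit <- lloyd_once(x, k)
    if (is.null(best) || fit$wss < best$wss - 1e-12) best <- fit
  }
  # canonical numbering on the good-minus-bad axis
  diffs <- best$centers[, 1] - best$centers[, 2]
  ord <- order(diffs, decreasing = TRUE)
  canon <- integer(k)
  if (k >= 3) {
    canon[ord[1]] <- 1L                    # good-preferring
    canon[ord[k]] <- 2L                    # bad-preferring
    canon[ord[seq(2, k - 1)]] <- seq(3L, k)
  } else {
    canon[ord] <- seq_len(k)
  }
  labels <- canon[best$labels]
  centroids <- best$centers[order(canon), , drop = FALSE]
  rownames(centroids) <- paste0("cluster", seq_len(k))
  structure(list(k = k, labels = labels, centroids = centroids,
                 wss = best$wss,
                 silhouette = mean_silhouette(x, labels),
                 seed = seed),
            class = "cluster_result")
}

#' Mean silhouette width of a labelling
#'
#' Silhouette width of point i is `(b_i - a_i) / max(a_i, b_i)`, with `a_i`
#' the mean Euclidean distance to the other members of its cluster and
#' `b_i` the smallest mean distance to another cluster. Singleton-cluster
#' points get width 0.
#'
#' @param x Numeric matrix of points.
#' @param labels Integer cluster labels.
#' @return Mean silhouette width in `[-1, 1]`.
#' @export
mean_silhouette <- function(x, labels) {
  x <- feature_matrix(x)
  n <- nrow(x)
  d <- as.matrix(dist(x))
  ks <- sort(unique(labels))
  if (length(ks) < 2) stop("silhouette needs at least two clusters")
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    if (sum(own) == 1) { s[i] <- 0; next }
    a <- sum(d[i, own]) / (sum(own) - 1)
    b <- min(vapply(ks[ks != labels[i]], function(kk) {
      mean(d[i, labels == kk])
    }, numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

#' Select the number of clusters by silhouette
#'
#' Runs [kmeans_assign()] for each candidate k and returns the k with the
#' highest mean silhouette width; exact ties go to the lowest k.
#'
#' @param features Feature data frame or matrix.
#' @param k_range Candidate cluster counts.
#' @param seed Integer seed (one independent substream per k).
#' @param n_restarts Restarts per k.
#' @return List with `k_best`, `silhouette_by_k` (named numeric), and
#'   `results` (one `cluster_result` per k).
#' @export
select_k <- function(features, k_range = 2:8, seed = 1, n_restarts = 50) {
  x <- feature_matrix(features)
  if (nrow(x) < max(k_range) + 1) stop("need more points than max(k_range)")
  results <- lapply(k_range, function(k) {
    kmeans_assign(x, k = k, seed = seed + k, n_restarts = n_restarts)
  })
  sil <- vapply(results, function(r) r$silhouette, numeric(1))
  names(sil) <- as.character(k_range)
  k_best <- k_range[which.max(sil)]   # which.max takes the first (lowest k)
  list(k_best = k_best, silhouette_by_k = sil,
       results = setNames(results, as.character(k_range)))
}

#' Accuracy of recovered cluster labels
#'
#' Agreement between recovered labels and generating archetypes under the
#' best of all label permutations (exhaustive relabel matching).
#'
#' @param labels Integer cluster labels.
#' @param truth Generating labels (any type).
#' @return Proportion of points correctly assigned under the best
#'   permutation.
#' @export
label_accuracy <- function(labels, truth) {
  lab_i <- as.integer(factor(labels))
  truth_i <- as.integer(factor(truth))
  k <- max(lab_i, truth_i)
  perms <- perm_all(k)
  best <- 0
  for (p in seq_len(nrow(perms))) {
    best <- max(best, mean(perms[p, ][lab_i] == truth_i))
  }
  best
}

perm_all <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- perm_all(n - 1)
  out <- matrix(0L, 0, n)
  for (i in seq_len(n)) {
    block <- cbind(i, sub + (sub >= i))
    out <- rbind(out, block)
  }
  out
}
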