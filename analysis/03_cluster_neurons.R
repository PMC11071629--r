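#!/usr/bin/env Rscript
# Response-type classification.
#
# Builds the 2D Z-feature (contralateral good versus bad response,
# 100-300 ms post target) per neuron, scans the cluster count by mean
# silhouette, and classifies neurons with canonical k-means labels.

suppressMessages(library(choicephys))
out <- "results/cluster"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

dirs <- list.dirs("results/population/sessions", recursive = FALSE)
stopifnot(length(dirs) > 0)
sessions <- lapply(dirs, read_session)
cat("loaded", length(sessions), "choice sessions\n")

features <- build_features(sessions)
sel <- select_k(features, k_range = 2:8, seed = 43)
cat("mean silhouette by k:\n")
print(round(sel$silhouette_by_k, 3))
cat("selected k =", sel$k_best, "\n")

clust <- kmeans_assign(features, k = sel$k_best, seed = 44)
acc <- label_accuracy(clust$labels, features$archetype)
cat(sprintf("cluster sizes: %s; agreement with generating archetypes: %.1f%%\n",
            paste(tabulate(clust$labels, clust$k), collapse = "/"),
            100 * acc))

write.table(cbind(features, cluster = clust$labels),
            file.path(out, "clusters.tsv"), sep = "\t",
            row.names = FALSE, quote = FALSE)
writeLines(jsonlite::toJSON(list(k_best = sel$k_best,
                                 silhouette_by_k = as.list(sel$silhouette_by_k),
                                 accuracy = acc,
                                 centroids = clust$centroids),
                            auto_unbox = TRUE, digits = NA),
           file.path(out, "silhouette.json"))
cat("wrote", file.path(out, "clusters.tsv"), "\n")
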