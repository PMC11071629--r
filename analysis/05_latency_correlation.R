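#!/usr/bin/env Rscript
# Saccade-latency quartile analysis.
#
# Per neuron and condition: trials split into latency quartiles, mean
# Z activity per quartile, and the correlation of group order with
# activity; per condition, the signed-rank test of the median
# correlation against zero. The good-preferring cluster is expected to
# show a negative median for contralateral good objects (stronger
# responses on short-latency trials).

suppressMessages(library(choicephys))
out <- "results/latency"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sessions <- lapply(list.dirs("results/population/sessions",
                             recursive = FALSE), read_session)
clusters <- read.delim("results/cluster/clusters.tsv")

tests <- list()
per_neuron <- list()
for (cl in sort(unique(clusters$cluster))) {
  members <- which(clusters$cluster == cl)
  if (length(members) < 6) next
  res <- latency_correlation_analysis(sessions[members])
  res$per_neuron$cluster <- cl
  res$tests$cluster <- cl
  per_neuron[[as.character(cl)]] <- res$per_neuron
  tests[[as.character(cl)]] <- res$tests
  gc <- res$tests[res$tests$condition == "good.contra", ]
  cat(sprintf("cluster %d good-contra: median r = %.3f, p = %.3g (n = %d)\n",
              cl, gc$median_r, gc$p, gc$n))
}

write.table(do.call(rbind, per_neuron),
            file.path(out, "latency_correlation.tsv"),
            sep = "\t", row.names = FALSE, quote = FALSE)
writeLines(jsonlite::toJSON(do.call(rbind, tests), dataframe = "rows",
                            auto_unbox = TRUE, digits = NA),
           file.path(out, "latency_test.json"))
cat("wrote", file.path(out, "latency_correlation.tsv"), "\n")
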