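#!/usr/bin/env Rscript
# Synthetic population.
#
# Simulates the default neuron population (38 good-preferring, 47
# bad-preferring, 53 visual archetypes, split across two monkeys with
# their respective behavioral policies), applies the baseline-rate
# inclusion filter, and writes every session as a plain-text bundle for
# the downstream stages.

suppressMessages(library(choicephys))
out <- "results/population"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

config <- pipeline_config(seed = 42)
pop <- simulate_population(config)
included <- vapply(pop$choice, inclusion_filter, logical(1))
cat(sprintf("simulated %d neurons; %d pass the <10 spikes/s filter\n",
            length(included), sum(included)))

for (i in which(included)) {
  s <- pop$choice[[i]]
  write_session(s, file.path(out, "sessions",
                             paste0(s$monkey_id, "_", s$neuron_id)))
  f <- pop$fixation[[i]]
  write_session(f, file.path(out, "fixation",
                             paste0(f$monkey_id, "_", f$neuron_id)))
}
writeLines(jsonlite::toJSON(list(seed = config$seed,
                                 n_neurons = as.list(config$n_neurons),
                                 n_included = sum(included),
                                 config_hash = choicephys:::config_hash(config)),
                            auto_unbox = TRUE),
           file.path(out, "population_meta.json"))
cat("wrote session bundles under", file.path(out, "sessions"), "\n")
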