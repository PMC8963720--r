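#!/usr/bin/env Rscript
# Stage 2 — score the attention-network effects.
#
# Reads the simulated ANT-I trials, cleans them (no-response trials marked
# incorrect; per-condition +-3 SD RT outlier exclusion), and computes each
# subject's alerting, orienting, and conflict effects plus overall RT.

library(ccckit)

trials <- read_trials("results/ant_trials.csv", "ant")
subjects <- read_trials("results/subjects.csv", "subjects")

effects <- score_ant_cohort(trials)
utils::write.csv(effects, "results/attention_effects.csv", row.names = FALSE)
log <- attr(effects, "removal_log")
writeLines(
  apply(log, 1, function(r) jsonlite::toJSON(as.list(r), auto_unbox = TRUE)),
  "results/ant_removal_log.jsonl"
)

m <- merge(subjects[, c("subject_id", "group")], effects, by = "subject_id")
cat("Per-group mean effects (ms):\n")
print(aggregate(
  cbind(alerting_rt, orienting_rt, conflict_rt, overall_rt) ~ group, m,
  function(x) round(mean(x), 1)
))
cat(sprintf(
  "%d RT outliers removed across %d subjects.\n",
  sum(log$n_removed), nrow(effects)
))
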