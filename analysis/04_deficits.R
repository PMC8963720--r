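#!/usr/bin/env Rscript
# Stage 4 — deficit frequencies.
#
# Cuts each measure at the worst decile of the TD group (10th percentile of
# CCC, 90th of the RT effects), flags per-subject deficits, and compares the
# deficit frequencies of the ADHD and subthreshold groups by Pearson
# chi-square.

library(ccckit)

subjects <- read_trials("results/subjects.csv", "subjects")
effects <- utils::read.csv("results/attention_effects.csv")
capacity <- utils::read.csv("results/capacity.csv")

m <- merge(subjects[, c("subject_id", "group")],
  merge(effects, capacity[, c("subject_id", "ccc_bps")], by = "subject_id"),
  by = "subject_id"
)
cuts <- compute_cutpoints(m[m$group == "TD", ])
flags <- merge(m[, c("subject_id", "group")], flag_deficits(m, cuts),
  by = "subject_id"
)
utils::write.csv(flags, "results/deficits.csv", row.names = FALSE)

tests <- lapply(stats::setNames(cuts$measure, cuts$measure), function(meas) {
  col <- paste0(meas, "_deficit")
  deficit_frequency_test(
    flags[[col]][flags$group == "ADHD"],
    flags[[col]][flags$group == "subthreshold"]
  )
})
jsonlite::write_json(
  list(
    cutpoints = cuts,
    tests = lapply(tests, function(d) {
      list(frequency = as.list(d$frequency), chi2 = d$chi2, p = d$p)
    })
  ),
  "results/deficit_summary.json",
  auto_unbox = TRUE, digits = NA, pretty = TRUE
)

for (meas in names(tests)) {
  d <- tests[[meas]]
  cat(sprintf(
    "%-13s ADHD %.1f%% vs subthreshold %.1f%% deficits: chi2 = %.2f, p = %.2f\n",
    meas, 100 * d$frequency[1], 100 * d$frequency[2], d$chi2, d$p
  ))
}
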