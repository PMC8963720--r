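#!/usr/bin/env Rscript
# Stage 6 — SVM classification.
#
# Linear soft-margin SVM over the five z-scored features (alerting, orienting,
# conflict effects, overall RT, CCC): the three direct group classifications
# with 1,000 repeated random 1/10 hold-outs and a shuffled-label baseline,
# the two cross-population predictions, and the feature-set comparison
# (attention effects vs CCC vs combined) for each direct contrast.

library(ccckit)

subjects <- read_trials("results/subjects.csv", "subjects")
effects <- utils::read.csv("results/attention_effects.csv")
capacity <- utils::read.csv("results/capacity.csv")

pops <- list(
  ADHD_vs_TD = c("ADHD", "TD"),
  sub_vs_TD = c("subthreshold", "TD"),
  ADHD_vs_sub = c("ADHD", "subthreshold")
)
feature_sets <- list(
  attention = c("alerting_rt", "orienting_rt", "conflict_rt", "overall_rt"),
  ccc = "ccc_bps",
  combined = c("alerting_rt", "orienting_rt", "conflict_rt", "overall_rt", "ccc_bps")
)

features_for <- function(groups, cols) {
  sel <- subjects[subjects$group %in% groups, , drop = FALSE]
  f <- build_features(effects, capacity, sel, features = cols)
  f$group <- factor(as.character(f$group), levels = groups)
  f
}

records <- list()
for (nm in names(pops)) {
  res_by_set <- lapply(feature_sets, function(cols) {
    repeated_cv(features_for(pops[[nm]], cols),
      n_repeats = 1000, seed = derive_seed(20220311L, match(nm, names(pops)))
    )
  })
  for (fs in names(res_by_set)) {
    r <- res_by_set[[fs]]
    cat(sprintf(
      "%-12s %-9s accuracy %.1f ± %.1f%% (chance %.1f%%), p vs baseline = %.3g\n",
      nm, fs, 100 * r$mean_accuracy, 100 * r$sd_accuracy,
      100 * r$chance_level, r$p
    ))
  }
  gain <- compare_feature_sets(res_by_set$combined, res_by_set$attention)
  cat(sprintf(
    "%-12s combined vs attention: t = %.2f, p = %.3g\n", nm, gain$t, gain$p
  ))
  records[[nm]] <- c(
    lapply(res_by_set, function(r) {
      list(
        mean_accuracy = r$mean_accuracy, sd_accuracy = r$sd_accuracy,
        chance_level = r$chance_level, baseline = r$mean_baseline, p = r$p
      )
    }),
    list(combined_vs_attention = gain)
  )
}

# cross-population predictions on the combined feature set
cross <- list(
  ADHD_to_sub = cross_classify(
    features_for(pops$ADHD_vs_TD, feature_sets$combined),
    features_for(pops$sub_vs_TD, feature_sets$combined),
    positive_levels = c("ADHD", "subthreshold"),
    n_repeats = 1000, seed = derive_seed(20220311L, 11L)
  ),
  sub_to_ADHD = cross_classify(
    features_for(pops$sub_vs_TD, feature_sets$combined),
    features_for(pops$ADHD_vs_TD, feature_sets$combined),
    positive_levels = c("subthreshold", "ADHD"),
    n_repeats = 1000, seed = derive_seed(20220311L, 12L)
  )
)
for (nm in names(cross)) {
  r <- cross[[nm]]
  cat(sprintf(
    "%-12s combined  accuracy %.1f ± %.1f%% (chance %.1f%%), p vs baseline = %.3g\n",
    nm, 100 * r$mean_accuracy, 100 * r$sd_accuracy, 100 * r$chance_level, r$p
  ))
  records[[nm]] <- list(
    mean_accuracy = r$mean_accuracy, sd_accuracy = r$sd_accuracy,
    chance_level = r$chance_level, baseline = r$mean_baseline, p = r$p
  )
}

jsonlite::write_json(records, "results/classification.json",
  auto_unbox = TRUE, digits = NA, pretty = TRUE
)
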