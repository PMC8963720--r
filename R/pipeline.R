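# End-to-end pipeline: simulate -> score -> estimate -> deficits -> infer ->
# classify -> report. Each stage is a thin call into the module functions so
# that the same computations serve interactive use, the analysis scripts, and
# the tests.

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()].
#' @param seed Global seed; all per-stage sub-seeds derive from it.
#' @param out_dir Output directory, or `NULL` to skip writing files.
#' @param n_repeats Cross-validation repeats for the classification stage.
#' @param deficit_literal Use the literal 10th percentile for every deficit
#'   cut (see [compute_cutpoints()]).
#' @param cv_mode `"subsample"` or `"kfold"` (see [repeated_cv()]).
#' @param scale_in_folds Fold-wise feature standardization (see
#'   [repeated_cv()]).
#' @param include_neutral Include neutral-flanker trials in overall RT.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(), seed = 20220311L,
                            out_dir = NULL, n_repeats = 1000L,
                            deficit_literal = FALSE,
                            cv_mode = "subsample", scale_in_folds = FALSE,
                            include_neutral = TRUE) {
  structure(
    list(
      cohort = cohort, seed = as.integer(seed), out_dir = out_dir,
      n_repeats = as.integer(n_repeats), deficit_literal = deficit_literal,
      cv_mode = cv_mode, scale_in_folds = scale_in_folds,
      include_neutral = include_neutral
    ),
    class = "pipeline_config"
  )
}

group_summary <- function(x, group, digits = 1) {
  g <- split(x, factor(group, levels = GROUPS))
  vapply(g, function(v) {
    sprintf(
      paste0("%.", digits, "f ± %.", digits, "f"),
      mean(v, na.rm = TRUE), stats::sd(v, na.rm = TRUE)
    )
  }, character(1))
}

#' Run the full analysis pipeline
#'
#' Generates (or accepts) a cohort, simulates both tasks for every subject,
#' scores attention effects, estimates capacities, computes deficit
#' frequencies (ADHD vs subthreshold, cuts from the TD decile norms), runs
#' the covariate-adjusted ANOVAs with Bonferroni post hocs and BIC Bayes
#' factors for each index, and runs the direct and cross-population SVM
#' classifications on the combined feature set. Fully deterministic given the
#' configuration seed. When `out_dir` is set, writes the subject, trial,
#' effects, capacity and deficit tables as CSV, the inference and
#' classification records as JSON, and a plain-text report with the
#' demographics, effects and classification summaries.
#'
#' @param config A [pipeline_config()].
#' @param subjects Optional pre-built cohort (from [generate_cohort()] or
#'   [read_trials()] with the subjects schema); by default generated from
#'   `config$cohort`.
#' @param trials Optional list with `ant` and `mft` trial tables; by default
#'   simulated from the cohort.
#' @return List: `subjects`, `trials`, `effects`, `capacity`, `measures`
#'   (merged per-subject analysis table), `cutpoints`, `deficits`,
#'   `deficit_tests`, `ancova`, `classification`, `report` (character
#'   vector), `exclusions`.
#' @export
run_pipeline <- function(config = pipeline_config(), subjects = NULL,
                         trials = NULL) {
  if (is.null(subjects)) {
    cohort_cfg <- config$cohort
    cohort_cfg$seed <- derive_seed(config$seed, 1L)
    subjects <- generate_cohort(cohort_cfg)
  }
  if (is.null(trials)) {
    trials <- simulate_cohort_trials(subjects, seed = derive_seed(config$seed, 2L))
  }

  effects <- score_ant_cohort(trials$ant, include_neutral = config$include_neutral)
  capacity <- estimate_ccc_cohort(trials$mft)

  measures <- merge(
    subjects[, intersect(
      c("subject_id", "group", "sex", "age", "school",
        "snap_inatt_n", "snap_hyper_n"),
      names(subjects)
    )],
    merge(effects, capacity[, c("subject_id", "ccc_bps", "boundary_flag")],
      by = "subject_id"
    ),
    by = "subject_id"
  )

  # deficit stage: TD decile cuts, ADHD vs subthreshold frequencies
  td <- measures[measures$group == "TD", , drop = FALSE]
  cutpoints <- compute_cutpoints(td, literal_decile = config$deficit_literal)
  flags <- flag_deficits(measures, cutpoints)
  flags <- merge(measures[, c("subject_id", "group")], flags, by = "subject_id")
  deficit_tests <- lapply(
    stats::setNames(cutpoints$measure, cutpoints$measure),
    function(m) {
      col <- paste0(m, "_deficit")
      deficit_frequency_test(
        flags[[col]][flags$group == "ADHD"],
        flags[[col]][flags$group == "subthreshold"]
      )
    }
  )

  # inference stage: ANCOVA per index with sex, age, school as covariates
  covs <- data.frame(
    sex = measures$sex, age = measures$age,
    school = as.character(measures$school)
  )
  indices <- c("alerting_rt", "orienting_rt", "conflict_rt", "overall_rt", "ccc_bps")
  anc <- lapply(stats::setNames(indices, indices), function(ix) {
    keep <- !is.na(measures[[ix]])
    a <- ancova(measures[[ix]][keep], measures$group[keep], covs[keep, , drop = FALSE])
    null_fit <- stats::lm(
      measures[[ix]][keep] ~ sex + age + school,
      data = covs[keep, , drop = FALSE]
    )
    a$bf10 <- bf_bic(
      as.numeric(stats::logLik(null_fit)),
      attr(stats::logLik(null_fit), "df"),
      as.numeric(stats::logLik(a$model)),
      attr(stats::logLik(a$model), "df"),
      sum(keep)
    )
    a$bf_label <- bf_label(a$bf10)
    a
  })

  # classification stage: combined feature set, direct + cross
  cls_seed <- derive_seed(config$seed, 3L)
  pops <- list(
    ADHD_vs_TD = c("ADHD", "TD"),
    sub_vs_TD = c("subthreshold", "TD"),
    ADHD_vs_sub = c("ADHD", "subthreshold")
  )
  feats <- lapply(pops, function(gg) {
    sel <- subjects[subjects$group %in% gg, , drop = FALSE]
    sel$group <- factor(sel$group, levels = gg)
    f <- build_features(effects, capacity, sel)
    f$group <- factor(as.character(f$group), levels = gg)
    f
  })
  classification <- lapply(
    stats::setNames(names(pops), names(pops)),
    function(nm) {
      repeated_cv(feats[[nm]],
        n_repeats = config$n_repeats, seed = derive_seed(cls_seed, match(nm, names(pops))),
        mode = config$cv_mode, scale_in_folds = config$scale_in_folds
      )
    }
  )
  classification$ADHD_to_sub <- cross_classify(
    feats$ADHD_vs_TD, feats$sub_vs_TD,
    positive_levels = c("ADHD", "subthreshold"),
    n_repeats = config$n_repeats, seed = derive_seed(cls_seed, 11L)
  )
  classification$sub_to_ADHD <- cross_classify(
    feats$sub_vs_TD, feats$ADHD_vs_TD,
    positive_levels = c("subthreshold", "ADHD"),
    n_repeats = config$n_repeats, seed = derive_seed(cls_seed, 12L)
  )

  exclusions <- list(
    ant_no_response = sum(!trials$ant$responded),
    ant_rt_outliers = sum(attr(effects, "removal_log")$n_removed),
    mft_no_response = sum(!trials$mft$responded),
    subjects_dropped_from_classification =
      unique(unlist(lapply(feats, attr, "dropped")))
  )

  report <- build_report(subjects, measures, deficit_tests, anc, classification)

  result <- list(
    subjects = subjects, trials = trials, effects = effects,
    capacity = capacity, measures = measures, cutpoints = cutpoints,
    deficits = flags, deficit_tests = deficit_tests, ancova = anc,
    classification = classification, report = report, exclusions = exclusions,
    config = config
  )
  if (!is.null(config$out_dir)) {
    write_pipeline_outputs(result, config$out_dir)
  }
  invisible(result)
}

build_report <- function(subjects, measures, deficit_tests, anc, classification) {
  grp <- factor(subjects$group, levels = GROUPS)
  n <- table(grp)
  male <- table(grp[subjects$sex == "M"])
  lines <- c(
    "== Cohort (Table 1 analogue) ==",
    sprintf(
      "%-13s n=%3d  M:F %d:%d  age %s  inattention %s  hyperactivity %s",
      GROUPS, n, male, n - male,
      group_summary(subjects$age, subjects$group),
      group_summary(subjects$snap_inatt_n, subjects$group),
      group_summary(subjects$snap_hyper_n, subjects$group)
    ),
    "",
    "== Attention effects and CCC (Table 2 analogue) =="
  )
  for (m in c("alerting_rt", "orienting_rt", "conflict_rt", "overall_rt")) {
    lines <- c(lines, sprintf(
      "%-13s %s", m,
      paste(group_summary(measures[[m]], measures$group), collapse = "  ")
    ))
  }
  lines <- c(lines, sprintf(
    "%-13s %s", "ccc_bps",
    paste(group_summary(measures$ccc_bps, measures$group, digits = 2), collapse = "  ")
  ))
  lines <- c(lines, "", "== Group ANCOVA (sex, age, school adjusted) ==")
  for (nm in names(anc)) {
    a <- anc[[nm]]
    lines <- c(lines, sprintf(
      "%-13s F(%d,%d) = %.2f, p = %.3g, partial eta2 = %.3f, BF10(BIC) = %.3g (%s)",
      nm, a$df_num, a$df_den, a$F, a$p, a$eta_sq, a$bf10, a$bf_label
    ))
  }
  lines <- c(lines, "", "== Deficit frequencies (ADHD vs subthreshold) ==")
  for (nm in names(deficit_tests)) {
    d <- deficit_tests[[nm]]
    lines <- c(lines, sprintf(
      "%-13s ADHD %d/%d (%.1f%%) vs sub %d/%d (%.1f%%), chi2 = %.2f, p = %.2f",
      nm, d$table[1, 1], sum(d$table[1, ]), 100 * d$frequency[1],
      d$table[2, 1], sum(d$table[2, ]), 100 * d$frequency[2], d$chi2, d$p
    ))
  }
  lines <- c(lines, "", "== SVM classification (Table 5 analogue) ==")
  for (nm in names(classification)) {
    r <- classification[[nm]]
    lines <- c(lines, sprintf(
      "%-12s accuracy %.1f ± %.1f%% (chance %.1f%%, baseline %.1f%%, p = %.3g)",
      nm, 100 * r$mean_accuracy, 100 * r$sd_accuracy,
      100 * r$chance_level, 100 * r$mean_baseline, r$p
    ))
  }
  lines
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_trials(result$subjects, file.path(out_dir, "subjects.csv"), "subjects")
  write_trials(result$trials$ant, file.path(out_dir, "ant_trials.csv"), "ant")
  write_trials(result$trials$mft, file.path(out_dir, "mft_trials.csv"), "mft")
  utils::write.csv(result$effects, file.path(out_dir, "attention_effects.csv"),
    row.names = FALSE
  )
  utils::write.csv(result$capacity, file.path(out_dir, "capacity.csv"),
    row.names = FALSE
  )
  utils::write.csv(result$deficits, file.path(out_dir, "deficits.csv"),
    row.names = FALSE
  )
  summary_json <- list(
    cutpoints = result$cutpoints,
    deficit_tests = lapply(result$deficit_tests, function(d) {
      list(
        counts = as.vector(d$table), frequency = as.list(d$frequency),
        chi2 = d$chi2, df = d$df, p = d$p
      )
    }),
    ancova = lapply(result$ancova, function(a) {
      list(
        F = a$F, df_num = a$df_num, df_den = a$df_den, p = a$p,
        eta_sq = a$eta_sq, bf10 = a$bf10, bf_label = a$bf_label
      )
    }),
    classification = lapply(result$classification, function(r) {
      list(
        mean_accuracy = r$mean_accuracy, sd_accuracy = r$sd_accuracy,
        chance_level = r$chance_level, mean_baseline = r$mean_baseline,
        t = r$t, p = r$p, n_repeats = length(r$accuracy)
      )
    }),
    exclusions = result$exclusions
  )
  jsonlite::write_json(summary_json, file.path(out_dir, "summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  writeLines(result$report, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}
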