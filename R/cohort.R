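# Synthetic cohort generation: demographics, SNAP-IV/ASQ informant reports,
# two-informant diagnosis, and latent task parameters per subject.

GROUPS <- c("ADHD", "subthreshold", "TD")

#' Default cohort configuration
#'
#' Per-group parameters for the synthetic cohort generator. Group order is
#' ADHD, subthreshold ADHD, TD throughout. Defaults reproduce the study
#' conditions: group sizes 39/34/36, sex ratios 29:10 / 24:10 / 17:19, ages
#' 10.6 +- 1.9 / 11.0 +- 1.9 / 11.6 +- 1.5 years, six schools, symptom-count
#' distributions per SNAP-IV subscale, ANT-I condition reaction-time means and
#' between-subject SDs, and true cognitive control capacity distributions
#' 2.73 +- 0.73 / 2.82 +- 0.71 / 3.26 +- 0.61 bps truncated at 0.3 bps.
#'
#' @param n_per_group Named integer vector of subjects per group.
#' @param seed Integer seed; every draw in [generate_cohort()] flows from it.
#' @param ... Overrides for any other configuration field.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_per_group = c(ADHD = 39L, subthreshold = 34L, TD = 36L),
                          seed = 20220311L, ...) {
  cfg <- list(
    n_per_group = n_per_group,
    male_prop = c(29 / 39, 24 / 34, 17 / 36),
    age_mean = c(10.6, 11.0, 11.6),
    age_sd = c(1.9, 1.9, 1.5),
    n_schools = 6L,
    # ANT-I latent effect parameters (ms): between-subject means and SDs
    congruent_mean = c(662.4, 594.4, 566.5),
    congruent_sd = c(137.2, 113.2, 129.5),
    alerting_mean = c(50.0, 37.4, 26.2),
    alerting_sd = c(49.4, 36.0, 19.7),
    orienting_mean = c(35.2, 31.8, 37.3),
    orienting_sd = c(44.5, 39.0, 31.8),
    conflict_mean = c(131.7, 136.1, 101.4),
    conflict_sd = c(57.4, 36.3, 33.7),
    # trial-level ex-Gaussian residual components (ms)
    rt_sigma = 60,
    rt_tau = 150,
    # ANT-I error model: baseline error rate and extra errors on incongruent
    err_base = 0.02,
    err_conflict = 0.065,
    # response lapses (no key press), shared across tasks
    lapse_mean = 0.02,
    lapse_sd = 0.015,
    lapse_max = 0.2,
    # MFT-M capacity model
    ccc_mean = c(2.73, 2.82, 3.26),
    ccc_sd = c(0.73, 0.71, 0.61),
    ccc_floor = 0.3,
    ceiling_mean = 0.97,
    ceiling_sd = 0.02,
    ceiling_range = c(0.80, 0.999),
    # SNAP-IV symptomatic item counts (items scored >= 2) and ASQ totals
    inatt_mean = c(6.4, 3.4, 0.2),
    inatt_sd = c(1.8, 1.3, 0.4),
    hyper_mean = c(4.6, 2.2, 0.1),
    hyper_sd = c(2.5, 1.7, 0.4),
    asq_mean = c(15, 13, 4),
    asq_sd = c(3, 2.5, 3),
    # teacher report = parent report with per-item integer perturbation
    teacher_noise = 0.05,
    asq_both_raters = TRUE,
    seed = seed
  )
  dots <- list(...)
  bad <- setdiff(names(dots), names(cfg))
  if (length(bad) > 0) {
    stop_field(bad[1], "unknown configuration field")
  }
  cfg[names(dots)] <- dots
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  if (length(cfg$n_per_group) != 3 || any(cfg$n_per_group <= 0)) {
    stop_field("n_per_group", "three positive counts required")
  }
  if (any(cfg$male_prop < 0 | cfg$male_prop > 1)) {
    stop_field("male_prop", "proportions must lie in [0, 1]")
  }
  for (f in c("age_sd", "congruent_sd", "alerting_sd", "orienting_sd",
              "conflict_sd", "ccc_sd", "inatt_sd", "hyper_sd", "asq_sd")) {
    if (any(cfg[[f]] < 0)) stop_field(f, "SDs must be >= 0")
  }
  if (any(cfg$ccc_mean <= 0)) stop_field("ccc_mean", "capacity means must be > 0")
  if (cfg$n_schools < 1) stop_field("n_schools", "at least one school")
  if (cfg$lapse_max < 0 || cfg$lapse_max > 0.2) {
    stop_field("lapse_max", "lapse rates are restricted to [0, 0.2]")
  }
  invisible(cfg)
}

# Draw SNAP item scores realising a target number of symptomatic items
# (score >= 2) out of n_items.
draw_items <- function(n_symptomatic, n_items) {
  scores <- ifelse(stats::runif(n_items) < 0.3, 1L, 0L)
  if (n_symptomatic > 0) {
    idx <- sample.int(n_items, n_symptomatic)
    scores[idx] <- ifelse(stats::runif(n_symptomatic) < 0.4, 3L, 2L)
  }
  scores
}

perturb_items <- function(items, rate) {
  flip <- stats::runif(length(items)) < rate
  items[flip] <- clamp(items[flip] + sample(c(-1L, 1L), sum(flip), replace = TRUE), 0L, 3L)
  items
}

#' Two-informant SNAP-IV / ASQ diagnosis
#'
#' Each rater's report is scored by counting items with at least two points in
#' the 9-item inattention and 9-item hyperactivity/impulsivity subscales. A
#' rater meets the ADHD symptom criterion when at least six items reach two
#' points in either subscale; the subthreshold criterion when 3-5 items reach
#' two points in either subscale without meeting the ADHD criterion. An ASQ
#' total of at least 10 is additionally required. The final label is ADHD only
#' when both raters meet the ADHD criteria; subthreshold when both raters meet
#' at least the subthreshold criteria (and not both meet ADHD); otherwise TD.
#'
#' The age-of-onset / two-setting impairment criterion of the full clinical
#' diagnosis has no observable counterpart in the simulated reports and is
#' treated as always satisfied.
#'
#' @param parent,teacher Informant reports: lists with integer vectors
#'   `inattention` (9 items, 0-3), `hyperactivity` (9 items, 0-3) and an
#'   `asq` total (0-30).
#' @param asq_both_raters If `TRUE` (default) the ASQ cut-off of 10 must be met
#'   by both raters; if `FALSE`, by at least one.
#' @return One of `"ADHD"`, `"subthreshold"`, `"TD"`.
#' @export
diagnose <- function(parent, teacher, asq_both_raters = TRUE) {
  score <- function(r, who) {
    if (length(r$inattention) != 9 || length(r$hyperactivity) != 9) {
      stop(sprintf("%s report must have 9 + 9 item scores", who), call. = FALSE)
    }
    items <- c(r$inattention, r$hyperactivity)
    if (any(items < 0 | items > 3 | items != round(items))) {
      stop(sprintf("%s report items must be integers in 0-3", who), call. = FALSE)
    }
    n_inatt <- sum(r$inattention >= 2)
    n_hyper <- sum(r$hyperactivity >= 2)
    level <- if (n_inatt >= 6 || n_hyper >= 6) {
      2L
    } else if (n_inatt >= 3 || n_hyper >= 3) {
      1L
    } else {
      0L
    }
    list(level = level, asq_ok = r$asq >= 10)
  }
  p <- score(parent, "parent")
  t <- score(teacher, "teacher")
  asq_ok <- if (asq_both_raters) p$asq_ok && t$asq_ok else p$asq_ok || t$asq_ok
  if (!asq_ok) {
    return("TD")
  }
  if (p$level == 2L && t$level == 2L) {
    return("ADHD")
  }
  if (p$level >= 1L && t$level >= 1L) {
    return("subthreshold")
  }
  "TD"
}

#' Generate a synthetic cohort
#'
#' Draws, for each intended group, demographics, parent SNAP-IV/ASQ reports
#' (symptomatic item counts constrained to the intended diagnostic band),
#' teacher reports as noisy copies of the parent reports, and the latent task
#' parameters that drive the trial simulators. The realised `group` label is
#' produced by applying [diagnose()] to the simulated informant reports, so
#' imperfect informant agreement can move borderline subjects between labels;
#' the intention is retained in `intended_group`.
#'
#' @param config A [cohort_config()].
#' @return Data.frame of subjects (one per row) with demographic, symptom and
#'   latent-parameter columns; the item-level informant reports are attached
#'   as the `"reports"` attribute (a list keyed by `subject_id`).
#' @export
generate_cohort <- function(config = cohort_config()) {
  validate_cohort_config(config)
  with_seed(config$seed, {
    rows <- list()
    reports <- list()
    sid <- 0L
    for (gi in seq_along(GROUPS)) {
      grp <- GROUPS[gi]
      for (s in seq_len(config$n_per_group[gi])) {
        sid <- sid + 1L
        id <- sprintf("S%03d", sid)

        sex <- if (stats::runif(1) < config$male_prop[gi]) "M" else "F"
        age <- round(stats::rnorm(1, config$age_mean[gi], config$age_sd[gi]), 1)
        age <- clamp(age, 6, 14)
        school <- sample.int(config$n_schools, 1)

        # symptomatic item counts, constrained to the intended band
        n_inatt <- clamp(round(stats::rnorm(1, config$inatt_mean[gi], config$inatt_sd[gi])), 0L, 9L)
        n_hyper <- clamp(round(stats::rnorm(1, config$hyper_mean[gi], config$hyper_sd[gi])), 0L, 9L)
        if (grp == "ADHD" && max(n_inatt, n_hyper) < 6) {
          if (n_inatt >= n_hyper) n_inatt <- 6L else n_hyper <- 6L
        } else if (grp == "subthreshold") {
          n_inatt <- min(n_inatt, 5L)
          n_hyper <- min(n_hyper, 5L)
          if (max(n_inatt, n_hyper) < 3) {
            if (n_inatt >= n_hyper) n_inatt <- 3L else n_hyper <- 3L
          }
        } else if (grp == "TD") {
          n_inatt <- min(n_inatt, 2L)
          n_hyper <- min(n_hyper, 2L)
        }

        asq_p <- clamp(round(stats::rnorm(1, config$asq_mean[gi], config$asq_sd[gi])), 0L, 30L)
        if (grp != "TD") asq_p <- max(asq_p, 10L)

        parent <- list(
          inattention = draw_items(n_inatt, 9L),
          hyperactivity = draw_items(n_hyper, 9L),
          opposition = draw_items(clamp(round(stats::rnorm(1, n_hyper / 2, 1)), 0L, 8L), 8L),
          asq = asq_p
        )
        teacher <- list(
          inattention = perturb_items(parent$inattention, config$teacher_noise),
          hyperactivity = perturb_items(parent$hyperactivity, config$teacher_noise),
          opposition = perturb_items(parent$opposition, config$teacher_noise),
          asq = clamp(asq_p + round(stats::rnorm(1, 0, 1.5)), 0L, 30L)
        )
        label <- diagnose(parent, teacher, config$asq_both_raters)

        # latent ANT-I parameters: a subject's congruent-condition mean RT and
        # the three network effect deltas; the base RT is chosen so that the
        # congruent cells (averaged over alerting and orienting levels) hit
        # the subject's congruent mean.
        congruent_i <- stats::rnorm(1, config$congruent_mean[gi], config$congruent_sd[gi])
        alert_i <- stats::rnorm(1, config$alerting_mean[gi], config$alerting_sd[gi])
        orient_i <- stats::rnorm(1, config$orienting_mean[gi], config$orienting_sd[gi])
        conflict_i <- stats::rnorm(1, config$conflict_mean[gi], config$conflict_sd[gi])
        base_rt <- max(250, congruent_i - alert_i / 2 - orient_i / 2)

        lapse <- clamp(stats::rnorm(1, config$lapse_mean, config$lapse_sd), 0, config$lapse_max)
        a0 <- clamp(
          stats::rnorm(1, config$ceiling_mean, config$ceiling_sd),
          config$ceiling_range[1], config$ceiling_range[2]
        )
        ccc <- rtnorm_lower(1, config$ccc_mean[gi], config$ccc_sd[gi], config$ccc_floor)

        rows[[sid]] <- data.frame(
          subject_id = id,
          group = label,
          intended_group = grp,
          sex = sex,
          age = age,
          school = school,
          snap_inatt_n = sum(parent$inattention >= 2),
          snap_hyper_n = sum(parent$hyperactivity >= 2),
          asq_parent = parent$asq,
          asq_teacher = teacher$asq,
          base_rt = base_rt,
          alerting_delta = alert_i,
          orienting_delta = orient_i,
          conflict_delta = conflict_i,
          rt_sigma = config$rt_sigma,
          rt_tau = config$rt_tau,
          err_base = config$err_base,
          err_conflict = config$err_conflict,
          lapse_rate = lapse,
          ceiling_acc = a0,
          true_ccc = ccc,
          stringsAsFactors = FALSE
        )
        reports[[id]] <- list(parent = parent, teacher = teacher)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "reports") <- reports
    attr(out, "config") <- config
    out
  })
}
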