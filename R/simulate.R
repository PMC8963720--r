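# Trial-level response simulators driven by a subject's latent parameters.

as_profile <- function(profile) {
  if (is.data.frame(profile)) {
    if (nrow(profile) != 1) stop("profile must be a single subject", call. = FALSE)
    profile <- as.list(profile)
  }
  profile
}

#' Simulate ANT-I responses for one subject
#'
#' Each trial's expected RT is the subject's base RT plus additive network
#' deltas: the alerting delta when no alerting signal is played, the orienting
#' delta on invalidly cued trials (half of it on uncued trials, which lack the
#' spatial pre-cue but also lack the invalid-cue reorienting cost), and the
#' conflict delta on incongruent-flanker trials. RTs are ex-Gaussian around
#' that mean; error probability is `err_base`, raised by `err_conflict` on
#' incongruent trials; a response lapse (no key press) occurs with probability
#' `lapse_rate`, and any RT beyond the 1700-ms response window is recorded as
#' a non-response. Error trials keep their drawn RT (error RTs are excluded by
#' the downstream analyses anyway).
#'
#' @param profile One subject row from [generate_cohort()] (or an equivalent
#'   list with fields `subject_id`, `base_rt`, `alerting_delta`,
#'   `orienting_delta`, `conflict_delta`, `rt_sigma`, `rt_tau`, `err_base`,
#'   `err_conflict`, `lapse_rate`).
#' @param schedule Schedule from [make_ant_schedule()].
#' @param seed Optional integer seed.
#' @return Data.frame of ANT trials: `subject_id`, `block`, `alerting`,
#'   `orienting`, `congruency`, `responded`, `rt_ms` (`NA` when no response),
#'   `correct`.
#' @export
simulate_ant <- function(profile, schedule, seed = NULL) {
  profile <- as_profile(profile)
  req <- c("block", "alerting", "orienting", "congruency")
  if (!all(req %in% names(schedule))) {
    stop("schedule must come from make_ant_schedule()", call. = FALSE)
  }
  n <- nrow(schedule)
  with_seed(seed, {
    mean_rt <- profile$base_rt +
      profile$alerting_delta * (schedule$alerting == "absent") +
      profile$orienting_delta * (schedule$orienting == "invalid") +
      profile$orienting_delta / 2 * (schedule$orienting == "none") +
      profile$conflict_delta * (schedule$congruency == "incongruent")
    mu <- mean_rt - profile$rt_tau
    rt <- rexgauss(n, mu, profile$rt_sigma, profile$rt_tau)
    rt <- pmax(rt, 120) # physiological floor
    p_err <- clamp(
      profile$err_base +
        profile$err_conflict * (schedule$congruency == "incongruent"),
      0, 1
    )
    correct <- stats::runif(n) >= p_err
    responded <- stats::runif(n) >= profile$lapse_rate & rt <= 1700
    data.frame(
      subject_id = profile$subject_id,
      block = schedule$block,
      alerting = schedule$alerting,
      orienting = schedule$orienting,
      congruency = schedule$congruency,
      responded = responded,
      rt_ms = ifelse(responded, rt, NA_real_),
      correct = correct & responded,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate MFT-M responses for one subject
#'
#' Correctness is Bernoulli with probability given by the capacity-limited
#' accuracy model [predict_accuracy()] at the trial's information amount,
#' exposure time, and the subject's true capacity and ceiling accuracy. A
#' response lapse occurs with probability `lapse_rate`; lapsed trials and RTs
#' beyond the 2500-ms window are non-responses (treated as errors downstream).
#' RTs are ex-Gaussian with a mean that grows with set size; they are carried
#' for completeness but not used by the capacity analyses.
#'
#' @param profile One subject row from [generate_cohort()] (fields
#'   `subject_id`, `true_ccc`, `ceiling_acc`, `lapse_rate`, `rt_sigma`,
#'   `rt_tau`).
#' @param schedule Schedule from [make_mft_schedule()].
#' @param seed Optional integer seed.
#' @return Data.frame of MFT trials: `subject_id`, `block`, `set_size`,
#'   `majority_n`, `minority_n`, `exposure_s`, `responded`, `rt_ms`,
#'   `correct`.
#' @export
simulate_mft <- function(profile, schedule, seed = NULL) {
  profile <- as_profile(profile)
  req <- c("block", "set_size", "majority_n", "minority_n", "exposure_s")
  if (!all(req %in% names(schedule))) {
    stop("schedule must come from make_mft_schedule()", call. = FALSE)
  }
  n <- nrow(schedule)
  with_seed(seed, {
    info <- group_search_information(schedule$majority_n, schedule$minority_n)
    p <- predict_accuracy(
      info, schedule$exposure_s, profile$true_ccc, profile$ceiling_acc
    )
    correct <- stats::runif(n) < p
    mu <- 650 + 80 * schedule$set_size - profile$rt_tau
    rt <- pmax(rexgauss(n, mu, profile$rt_sigma, profile$rt_tau), 150)
    responded <- stats::runif(n) >= profile$lapse_rate & rt <= 2500
    data.frame(
      subject_id = profile$subject_id,
      block = schedule$block,
      set_size = schedule$set_size,
      majority_n = schedule$majority_n,
      minority_n = schedule$minority_n,
      exposure_s = schedule$exposure_s,
      responded = responded,
      rt_ms = ifelse(responded, rt, NA_real_),
      correct = correct & responded,
      stringsAsFactors = FALSE
    )
  })
}

#' Simulate both tasks for every subject in a cohort
#'
#' Per-subject sub-seeds are derived deterministically from `seed`, so the
#' result is reproducible and independent of subject order within each task.
#'
#' @param subjects Cohort data.frame from [generate_cohort()].
#' @param seed Integer seed.
#' @return List with `ant` and `mft` trial data.frames covering all subjects.
#' @export
simulate_cohort_trials <- function(subjects, seed = 20220311L) {
  ant <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    sched <- make_ant_schedule(seed = derive_seed(seed, 2L * i))
    simulate_ant(subjects[i, , drop = FALSE], sched,
      seed = derive_seed(seed, 2L * i + 1L)
    )
  }))
  mft <- do.call(rbind, lapply(seq_len(nrow(subjects)), function(i) {
    sched <- make_mft_schedule(seed = derive_seed(seed, 10000L + 2L * i))
    simulate_mft(subjects[i, , drop = FALSE], sched,
      seed = derive_seed(seed, 10001L + 2L * i)
    )
  }))
  list(ant = ant, mft = mft)
}
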