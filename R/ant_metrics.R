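# Cleaning of ANT-I trials and computation of per-subject attention-network
# effect scores.

ant_cell_key <- function(trials) {
  interaction(trials$alerting, trials$orienting, trials$congruency, drop = FALSE)
}

#' Clean one subject's ANT-I trials
#'
#' Builds the two analysis pools: an accuracy pool in which trials without a
#' response are marked incorrect, and an RT pool restricted to correct,
#' responded trials whose RT lies within mean +- 3 SD of the same subject's
#' correct-trial RTs in the same design cell (18 cells: alerting x orienting x
#' congruency). A cell with fewer than two correct trials cannot support an
#' outlier criterion and is passed through unfiltered (logged).
#'
#' @param trials ANT trial data.frame for a single subject.
#' @return List with `rt_pool` (retained correct trials), `acc_pool` (all
#'   trials with column `correct_adj`), and `removal_log` (per-cell counts of
#'   correct trials, outliers removed, and whether filtering was applied).
#' @export
clean_ant_trials <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0) {
    stop("no trials supplied", call. = FALSE)
  }
  if (length(unique(trials$subject_id)) > 1) {
    stop("clean_ant_trials() expects trials from one subject", call. = FALSE)
  }
  acc_pool <- trials
  acc_pool$correct_adj <- as.logical(trials$correct) & as.logical(trials$responded)

  cand <- trials[acc_pool$correct_adj & !is.na(trials$rt_ms), , drop = FALSE]
  key <- ant_cell_key(cand)
  keep <- logical(nrow(cand))
  log_rows <- list()
  for (cell in levels(key)) {
    idx <- which(key == cell)
    if (length(idx) == 0) next
    rts <- cand$rt_ms[idx]
    if (length(idx) < 2) {
      keep[idx] <- TRUE
      log_rows[[cell]] <- data.frame(
        cell = cell, n_correct = length(idx), n_removed = 0L,
        filtered = FALSE, stringsAsFactors = FALSE
      )
      next
    }
    m <- mean(rts)
    s <- stats::sd(rts)
    ok <- abs(rts - m) <= 3 * s
    keep[idx] <- ok
    log_rows[[cell]] <- data.frame(
      cell = cell, n_correct = length(idx), n_removed = sum(!ok),
      filtered = TRUE, stringsAsFactors = FALSE
    )
  }
  removal_log <- do.call(rbind, log_rows)
  rownames(removal_log) <- NULL
  list(
    rt_pool = cand[keep, , drop = FALSE],
    acc_pool = acc_pool,
    removal_log = removal_log
  )
}

mean_or_na <- function(x) if (length(x) == 0) NA_real_ else mean(x)

#' Compute attention-network effects for one subject
#'
#' Subtraction scores over the cleaned pools, in the direction "worse minus
#' better" so that a larger effect indicates a worse function:
#'
#' * alerting  = mean(no alerting signal) - mean(with alerting signal)
#' * orienting = mean(invalid cue) - mean(valid cue)
#' * conflict  = mean(incongruent) - mean(congruent)
#'
#' RT effects use the retained correct trials; accuracy effects apply the same
#' subtractions to per-condition accuracy with no-response trials counted as
#' errors. `overall_rt` is the mean over all retained RT trials (optionally
#' excluding neutral-flanker trials).
#'
#' @param cleaned Output of [clean_ant_trials()].
#' @param include_neutral Include neutral-flanker trials in `overall_rt`
#'   (default `TRUE`).
#' @return One-row data.frame (`AttentionEffects`): `subject_id`,
#'   `alerting_rt`, `orienting_rt`, `conflict_rt`, `alerting_acc`,
#'   `orienting_acc`, `conflict_acc`, `overall_rt`, `n_trials_rt_used`,
#'   `n_outliers_removed`. An effect whose defining trials are absent is `NA`.
#' @export
compute_attention_effects <- function(cleaned, include_neutral = TRUE) {
  rt <- cleaned$rt_pool
  acc <- cleaned$acc_pool

  eff_rt <- function(set_a, set_b) {
    a <- mean_or_na(rt$rt_ms[set_a(rt)])
    b <- mean_or_na(rt$rt_ms[set_b(rt)])
    a - b
  }
  eff_acc <- function(set_a, set_b) {
    a <- mean_or_na(acc$correct_adj[set_a(acc)])
    b <- mean_or_na(acc$correct_adj[set_b(acc)])
    a - b
  }
  no_sig <- function(d) d$alerting == "absent"
  sig <- function(d) d$alerting == "present"
  invalid <- function(d) d$orienting == "invalid"
  valid <- function(d) d$orienting == "valid"
  incong <- function(d) d$congruency == "incongruent"
  cong <- function(d) d$congruency == "congruent"

  overall_pool <- if (include_neutral) rt else rt[rt$congruency != "neutral", , drop = FALSE]

  data.frame(
    subject_id = acc$subject_id[1],
    alerting_rt = eff_rt(no_sig, sig),
    orienting_rt = eff_rt(invalid, valid),
    conflict_rt = eff_rt(incong, cong),
    alerting_acc = eff_acc(no_sig, sig),
    orienting_acc = eff_acc(invalid, valid),
    conflict_acc = eff_acc(incong, cong),
    overall_rt = mean_or_na(overall_pool$rt_ms),
    n_trials_rt_used = nrow(rt),
    n_outliers_removed = sum(cleaned$removal_log$n_removed),
    stringsAsFactors = FALSE
  )
}

#' Score ANT-I effects for every subject in a trial table
#'
#' @param trials ANT trial data.frame for many subjects.
#' @param include_neutral Passed to [compute_attention_effects()].
#' @return Data.frame with one `AttentionEffects` row per subject; the
#'   concatenated per-cell removal logs are attached as attribute
#'   `"removal_log"`.
#' @export
score_ant_cohort <- function(trials, include_neutral = TRUE) {
  ids <- unique(trials$subject_id)
  logs <- list()
  out <- do.call(rbind, lapply(ids, function(id) {
    cleaned <- clean_ant_trials(trials[trials$subject_id == id, , drop = FALSE])
    logs[[id]] <<- cbind(subject_id = id, cleaned$removal_log)
    compute_attention_effects(cleaned, include_neutral = include_neutral)
  }))
  rownames(out) <- NULL
  attr(out, "removal_log") <- do.call(rbind, logs)
  out
}
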