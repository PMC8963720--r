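# Fixed factorial trial schedules for the two tasks. Counts are design
# constants; only the within-block presentation order is random.

#' Build the ANT-I trial schedule
#'
#' 2 (alerting signal: present/absent) x 3 (orienting cue: valid/invalid/none)
#' x 3 (flanker congruency: congruent/incongruent/neutral) = 18 conditions,
#' four trials of each combination per block, two blocks of 72 trials (144
#' total). Trial order is randomised within each block.
#'
#' Timing internals of the task (fixation jitter 400-1600 ms, 450/500-ms SOAs,
#' 4450-ms fixed trial length) do not influence the simulated responses and
#' are recorded as attributes only.
#'
#' @param seed Optional integer seed for the within-block shuffles.
#' @return Data.frame with columns `block`, `trial`, `alerting`, `orienting`,
#'   `congruency`.
#' @export
make_ant_schedule <- function(seed = NULL) {
  cells <- expand.grid(
    alerting = c("present", "absent"),
    orienting = c("valid", "invalid", "none"),
    congruency = c("congruent", "incongruent", "neutral"),
    stringsAsFactors = FALSE
  )
  block_trials <- cells[rep(seq_len(nrow(cells)), each = 4), , drop = FALSE]
  out <- with_seed(seed, {
    do.call(rbind, lapply(1:2, function(b) {
      ord <- sample.int(nrow(block_trials))
      data.frame(
        block = b,
        trial = seq_len(nrow(block_trials)),
        block_trials[ord, , drop = FALSE],
        row.names = NULL,
        stringsAsFactors = FALSE
      )
    }))
  })
  attr(out, "timing") <- list(
    fixation_ms = c(400, 1600), alert_soa_ms = 450, cue_soa_ms = 500,
    response_window_ms = 1700, trial_length_ms = 4450
  )
  out
}

#' Build the MFT-M trial schedule
#'
#' 3 (exposure time: 0.25/0.5/1 s) x 3 (set size: 1/3/5) combinations, one
#' block of 36 trials each (324 trials total). Within a block the set ratios
#' of the block's set size occur with equal probability per ratio type:
#' 36 trials of 1:0 (set size 1); 18 each of 3:0 and 2:1 (set size 3);
#' 12 each of 5:0, 4:1 and 3:2 (set size 5). Trial order is randomised within
#' each block.
#'
#' @param seed Optional integer seed for the within-block shuffles.
#' @return Data.frame with columns `block`, `trial`, `set_size`, `majority_n`,
#'   `minority_n`, `exposure_s`.
#' @export
make_mft_schedule <- function(seed = NULL) {
  ratios <- list(
    `1` = data.frame(majority_n = 1L, minority_n = 0L, n = 36L),
    `3` = data.frame(majority_n = c(3L, 2L), minority_n = c(0L, 1L), n = 18L),
    `5` = data.frame(majority_n = c(5L, 4L, 3L), minority_n = c(0L, 1L, 2L), n = 12L)
  )
  blocks <- expand.grid(set_size = c(1L, 3L, 5L), exposure_s = c(0.25, 0.5, 1))
  out <- with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(blocks)), function(b) {
      ss <- blocks$set_size[b]
      r <- ratios[[as.character(ss)]]
      tr <- r[rep(seq_len(nrow(r)), times = r$n), c("majority_n", "minority_n")]
      tr <- tr[sample.int(nrow(tr)), , drop = FALSE]
      data.frame(
        block = b,
        trial = seq_len(nrow(tr)),
        set_size = ss,
        tr,
        exposure_s = blocks$exposure_s[b],
        row.names = NULL,
        stringsAsFactors = FALSE
      )
    }))
  })
  attr(out, "timing") <- list(
    fixation_ms = c(0, 500), mask_ms = 500, response_window_ms = 2500,
    feedback_ms = 750, trial_length_ms = 5750
  )
  out
}
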