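# Deficit flagging against typically-developing decile norms and
# between-group deficit-frequency comparison.

DEFICIT_MEASURES <- c("alerting_rt", "orienting_rt", "conflict_rt", "ccc_bps")

#' Normative deficit cut points from the TD group
#'
#' The cut point for each measure is the decile of the TD distribution lying
#' in the deficit tail: since a larger network effect means a worse function
#' and a lower capacity means worse cognitive control, the default places the
#' cut at the 90th percentile of each RT effect and the 10th percentile of
#' CCC. Setting `literal_decile = TRUE` instead uses the literal 10th
#' percentile for every measure. Quantiles use linear interpolation between
#' order statistics (`stats::quantile` type 7).
#'
#' @param td_measures Data.frame of TD subjects containing the measure
#'   columns.
#' @param measures Character vector of measure column names.
#' @param directions Named character vector, `"above"` (above-cut is deficit)
#'   or `"below"`, per measure. Defaults: `"above"` for effects, `"below"`
#'   for `ccc_bps`.
#' @param literal_decile Use the 10th percentile for all measures regardless
#'   of direction.
#' @return Data.frame (`DeficitCutpoints`): `measure`, `cut`, `direction`,
#'   `n_reference`.
#' @export
compute_cutpoints <- function(td_measures,
                              measures = DEFICIT_MEASURES,
                              directions = NULL,
                              literal_decile = FALSE) {
  if (is.null(directions)) {
    directions <- ifelse(measures == "ccc_bps", "below", "above")
    names(directions) <- measures
  }
  rows <- lapply(measures, function(m) {
    x <- td_measures[[m]]
    if (is.null(x)) stop("measure column missing: ", m, call. = FALSE)
    x <- x[!is.na(x)]
    if (length(x) < 10) {
      stop("need at least 10 TD subjects with non-missing ", m, call. = FALSE)
    }
    dir <- directions[[m]]
    prob <- if (literal_decile || dir == "below") 0.10 else 0.90
    data.frame(
      measure = m,
      cut = unname(stats::quantile(x, prob, type = 7)),
      direction = dir,
      n_reference = length(x),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, rows)
}

#' Flag per-subject deficits against cut points
#'
#' A deficit is flagged when the measure lies strictly beyond the cut in the
#' deficit direction (ties at the cut are not deficits). Missing measures
#' yield missing flags.
#'
#' @param measures Data.frame with a `subject_id` column and the measure
#'   columns named in `cutpoints`.
#' @param cutpoints Output of [compute_cutpoints()].
#' @return Data.frame: `subject_id` plus one logical `<measure>_deficit`
#'   column per measure.
#' @export
flag_deficits <- function(measures, cutpoints) {
  out <- data.frame(subject_id = measures$subject_id, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cutpoints))) {
    m <- cutpoints$measure[i]
    x <- measures[[m]]
    flag <- if (cutpoints$direction[i] == "below") {
      x < cutpoints$cut[i]
    } else {
      x > cutpoints$cut[i]
    }
    out[[paste0(m, "_deficit")]] <- flag
  }
  out
}

#' Compare deficit frequencies between two groups
#'
#' Builds the 2 x 2 deficit-by-group contingency table and applies the
#' Pearson chi-square test of independence (no continuity correction).
#'
#' @param flags_a,flags_b Logical deficit flags for the two groups (`NA`s
#'   dropped).
#' @param labels Group names for the table.
#' @return List: `table` (2 x 2 counts), `chi2`, `df`, `p`, and `frequency`
#'   (named proportion flagged per group). With a degenerate table (a zero
#'   margin) the statistic is `NA` and `reason` explains why.
#' @export
deficit_frequency_test <- function(flags_a, flags_b,
                                   labels = c("ADHD", "subthreshold")) {
  flags_a <- flags_a[!is.na(flags_a)]
  flags_b <- flags_b[!is.na(flags_b)]
  if (length(flags_a) == 0 || length(flags_b) == 0) {
    stop("both groups must contain flagged subjects", call. = FALSE)
  }
  tab <- rbind(
    c(sum(flags_a), sum(!flags_a)),
    c(sum(flags_b), sum(!flags_b))
  )
  dimnames(tab) <- list(group = labels, deficit = c("yes", "no"))
  test <- chisq_independence(tab)
  freq <- c(mean(flags_a), mean(flags_b))
  names(freq) <- labels
  c(list(table = tab, frequency = freq), test)
}
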