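# Information quantification for MFT-M set ratios and maximum-likelihood
# estimation of cognitive control capacity (CCC, bits per second).

#' Information content of a majority-judgement set under the grouping-search
#' strategy
#'
#' In the majority function task the observer reports the majority direction of
#' `m + k` arrows (`m` pointing with the majority, `k` with the minority). The
#' grouping-search strategy samples subsets ("groups") of size
#' `g = (m + k + 1) / 2` at random (with replacement of groups) until a
#' homogeneous group is found; its direction is the majority direction. The
#' expected number of samples is `E_S = C(n, g) / (C(m, g) + C(k, g))`
#' (hypergeometric probability of a homogeneous group), and the information
#' conveyed by the set is
#'
#'   `I = log2(g * E_S)`  bits,
#'
#' i.e. the log cost of the search: groups sampled times arrows per group.
#' For the six ratios used in the task (1:0, 3:0, 2:1, 5:0, 4:1, 3:2) this
#' gives 0, 1.00, 2.58, 1.58, 2.91 and 4.91 bits (2 dp).
#'
#' @param m Majority arrow count (positive integer).
#' @param k Minority arrow count (non-negative integer, `k < m`); the set size
#'   `m + k` must be odd so that a majority exists.
#' @return Information amount in bits (vectorised over `m`, `k`).
#' @examples
#' group_search_information(3, 2) # ~4.91 bits
#' group_search_information(1, 0) # 0 bits
#' @export
group_search_information <- function(m, k) {
  if (length(m) != length(k)) {
    lng <- max(length(m), length(k))
    m <- rep_len(m, lng)
    k <- rep_len(k, lng)
  }
  if (any(is.na(m)) || any(is.na(k))) {
    stop("m and k must be non-missing counts", call. = FALSE)
  }
  if (any(m != round(m)) || any(k != round(k))) {
    stop("m and k must be integer counts", call. = FALSE)
  }
  if (any(k < 0) || any(m <= k)) {
    stop("require m > k >= 0 (a strict majority)", call. = FALSE)
  }
  n <- m + k
  if (any(n %% 2 == 0)) {
    stop("set size m + k must be odd", call. = FALSE)
  }
  g <- (n + 1) / 2
  p_hom <- (choose(m, g) + choose(k, g)) / choose(n, g)
  e_s <- 1 / p_hom
  log2(g * e_s)
}

#' Expected number of group samples until a homogeneous group
#'
#' Closed-form companion of [group_search_information()]; exposed for
#' diagnostics and for cross-checking against simulation.
#'
#' @inheritParams group_search_information
#' @return Expected sample count `E_S >= 1`.
#' @export
expected_group_samples <- function(m, k) {
  n <- m + k
  g <- (n + 1) / 2
  choose(n, g) / (choose(m, g) + choose(k, g))
}

#' Condition table for the MFT-M design
#'
#' All 18 cells of the 3 (exposure time) x 6 (set ratio) design with their
#' information amounts and information rates.
#'
#' @param exposure_s Exposure times in seconds.
#' @return A data.frame with columns `set_size`, `majority_n`, `minority_n`,
#'   `exposure_s`, `info_bits`, `info_rate_bps`.
#' @export
mft_info_conditions <- function(exposure_s = c(0.25, 0.5, 1)) {
  ratios <- data.frame(
    majority_n = c(1L, 3L, 2L, 5L, 4L, 3L),
    minority_n = c(0L, 0L, 1L, 0L, 1L, 2L)
  )
  out <- merge(ratios, data.frame(exposure_s = exposure_s))
  out$set_size <- out$majority_n + out$minority_n
  out$info_bits <- group_search_information(out$majority_n, out$minority_n)
  out$info_rate_bps <- out$info_bits / out$exposure_s
  out[order(out$set_size, -out$minority_n, out$exposure_s),
    c("set_size", "majority_n", "minority_n", "exposure_s",
      "info_bits", "info_rate_bps"),
    drop = FALSE
  ]
}

#' Predicted response accuracy under the capacity-limited processing model
#'
#' Accuracy stays at the subject's ceiling `a0` while the information load can
#' be processed within the exposure time (`I <= C * T`), and declines linearly
#' toward the binary guessing floor 0.5 in the processed fraction once the
#' input rate exceeds capacity:
#'
#'   `p = a0`                           if `I <= C * T`
#'   `p = 0.5 + (a0 - 0.5) * C * T / I` otherwise.
#'
#' The knee of this function in information rate `I / T` is the capacity `C` —
#' the rate at which accuracy starts to drop. The form is continuous in all
#' arguments, weakly decreasing in `I` and increasing in `T` and `C`.
#'
#' @param info_bits Information amount `I` in bits (>= 0).
#' @param exposure_s Exposure time `T` in seconds (> 0).
#' @param ccc_bps Capacity `C` in bits per second (> 0).
#' @param ceiling_acc Ceiling accuracy `a0` in (0.5, 1].
#' @return Predicted probability of a correct response (vectorised).
#' @examples
#' predict_accuracy(4.91, 0.25, 3, 0.99) # 0.5 + 0.49 * 0.75 / 4.91
#' @export
predict_accuracy <- function(info_bits, exposure_s, ccc_bps, ceiling_acc) {
  if (any(info_bits < 0)) stop("info_bits must be >= 0", call. = FALSE)
  if (any(exposure_s <= 0)) stop("exposure_s must be > 0", call. = FALSE)
  if (any(ccc_bps <= 0)) stop("ccc_bps must be > 0", call. = FALSE)
  if (any(ceiling_acc <= 0.5) || any(ceiling_acc > 1)) {
    stop("ceiling_acc must lie in (0.5, 1]", call. = FALSE)
  }
  load <- ccc_bps * exposure_s
  ifelse(info_bits <= load,
    ceiling_acc + numeric(length(info_bits)),
    0.5 + (ceiling_acc - 0.5) * load / info_bits
  )
}

# Bernoulli log-likelihood of capacity C for per-cell correct counts.
ccc_loglik <- function(ccc, cells, ceiling_acc) {
  vapply(ccc, function(C) {
    p <- predict_accuracy(cells$info_bits, cells$exposure_s, C, ceiling_acc)
    p <- clamp(p, 1e-9, 1 - 1e-9)
    sum(cells$n_correct * log(p) + (cells$n_wrong) * log(1 - p))
  }, numeric(1))
}

#' Estimate a subject's cognitive control capacity by maximum likelihood
#'
#' Trials without a response are counted as errors. The ceiling accuracy `a0`
#' is fixed from the subject's accuracy in the zero-information 1:0 conditions
#' (clipped to \[0.51, 0.999\]), leaving the capacity `C` as the single free
#' parameter, which is found by maximising the Bernoulli log-likelihood of the
#' observed correctness under [predict_accuracy()] over a log-spaced grid on
#' \[`grid_min`, `grid_max`\] refined locally to `grid_step` resolution.
#'
#' A subject correct on effectively every trial at every information rate
#' carries no information about where accuracy starts to drop: the likelihood
#' is maximised at the upper grid bound and `boundary_flag` is set to
#' `"upper"` (symmetrically `"lower"` for at-chance data). Such estimates are
#' censored, not errors.
#'
#' @param trials Data.frame of MFT-M trials for one subject with columns
#'   `majority_n`, `minority_n`, `exposure_s`, `responded`, `correct`.
#' @param grid_min,grid_max Capacity search bounds in bits per second.
#' @param grid_step Resolution of the final estimate (bps).
#' @param coarse_n Number of log-spaced points in the first-pass grid.
#' @param ceiling_acc Optional fixed `a0`; by default estimated from the 1:0
#'   trials.
#' @return A one-row data.frame (`CapacityEstimate`): `ccc_bps`, `ceiling_acc`,
#'   `log_likelihood`, `boundary_flag` (`"none"`, `"lower"`, `"upper"`),
#'   `n_trials`, plus the grid bounds used.
#' @export
estimate_ccc <- function(trials, grid_min = 0.05, grid_max = 10,
                         grid_step = 0.01, coarse_n = 200,
                         ceiling_acc = NULL) {
  req <- c("majority_n", "minority_n", "exposure_s", "responded", "correct")
  miss <- setdiff(req, names(trials))
  if (length(miss) > 0) {
    stop("trials input lacks columns: ", paste(miss, collapse = ", "),
      call. = FALSE
    )
  }
  if (nrow(trials) == 0) stop("no trials supplied", call. = FALSE)

  # no-response trials are error responses for the accuracy model
  correct <- as.logical(trials$correct) & as.logical(trials$responded)
  info <- group_search_information(trials$majority_n, trials$minority_n)
  key <- paste(signif(info, 10), trials$exposure_s)
  cells <- data.frame(
    info_bits = tapply(info, key, `[`, 1),
    exposure_s = tapply(trials$exposure_s, key, `[`, 1),
    n_correct = as.vector(tapply(correct, key, sum)),
    n = as.vector(tapply(correct, key, length))
  )
  cells$n_wrong <- cells$n - cells$n_correct
  if (nrow(cells) < 6) {
    stop("need trials in at least 6 of the 18 (ratio, exposure) cells",
      call. = FALSE
    )
  }

  if (is.null(ceiling_acc)) {
    zero <- cells$info_bits == 0
    if (!any(zero)) {
      stop("no zero-information (1:0) trials to fix the ceiling accuracy; ",
        "supply ceiling_acc explicitly",
        call. = FALSE
      )
    }
    ceiling_acc <- sum(cells$n_correct[zero]) / sum(cells$n[zero])
    ceiling_acc <- clamp(ceiling_acc, 0.51, 0.999)
  }

  coarse <- exp(seq(log(grid_min), log(grid_max), length.out = coarse_n))
  ll <- ccc_loglik(coarse, cells, ceiling_acc)
  i <- which.max(ll)
  lo <- coarse[max(1L, i - 1L)]
  hi <- coarse[min(coarse_n, i + 1L)]
  fine <- unique(c(seq(lo, hi, by = grid_step), hi))
  llf <- ccc_loglik(fine, cells, ceiling_acc)
  j <- which.max(llf)
  est <- fine[j]
  best_ll <- llf[j]

  flag <- "none"
  if (est <= grid_min + grid_step / 2) flag <- "lower"
  if (est >= grid_max - grid_step) flag <- "upper"

  data.frame(
    ccc_bps = est,
    ceiling_acc = ceiling_acc,
    log_likelihood = best_ll,
    boundary_flag = flag,
    n_trials = nrow(trials),
    grid_min = grid_min,
    grid_max = grid_max,
    grid_step = grid_step,
    stringsAsFactors = FALSE
  )
}

#' Estimate CCC for every subject in a trial table
#'
#' @param trials Data.frame of MFT-M trials for many subjects (must contain a
#'   `subject_id` column in addition to the columns used by [estimate_ccc()]).
#' @param ... Passed to [estimate_ccc()].
#' @return Data.frame with one row per subject: `subject_id` plus the
#'   `CapacityEstimate` fields.
#' @export
estimate_ccc_cohort <- function(trials, ...) {
  stopifnot("subject_id" %in% names(trials))
  ids <- unique(trials$subject_id)
  out <- do.call(rbind, lapply(ids, function(id) {
    est <- estimate_ccc(trials[trials$subject_id == id, , drop = FALSE], ...)
    cbind(subject_id = id, est, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
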