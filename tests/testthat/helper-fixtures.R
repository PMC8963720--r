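# Shared fixtures, built once per test run. The "default fixture" is the
# study-sized cohort under the package's default configuration (seeds
# included), with both tasks simulated and scored.

.fixture_env <- new.env(parent = emptyenv())

default_fixture <- function() {
  if (!exists("fx", envir = .fixture_env)) {
    cohort <- generate_cohort(cohort_config())
    trials <- simulate_cohort_trials(cohort)
    effects <- score_ant_cohort(trials$ant)
    capacity <- estimate_ccc_cohort(trials$mft)
    .fixture_env$fx <- list(
      cohort = cohort, trials = trials, effects = effects, capacity = capacity
    )
  }
  .fixture_env$fx
}

# Minimal latent profile for the trial simulators, with overridable fields.
make_profile <- function(subject_id = "P01", base_rt = 600,
                         alerting_delta = 40, orienting_delta = 30,
                         conflict_delta = 100, rt_sigma = 60, rt_tau = 150,
                         err_base = 0.02, err_conflict = 0.065,
                         lapse_rate = 0, ceiling_acc = 0.97, true_ccc = 3) {
  list(
    subject_id = subject_id, base_rt = base_rt,
    alerting_delta = alerting_delta, orienting_delta = orienting_delta,
    conflict_delta = conflict_delta, rt_sigma = rt_sigma, rt_tau = rt_tau,
    err_base = err_base, err_conflict = err_conflict,
    lapse_rate = lapse_rate, ceiling_acc = ceiling_acc, true_ccc = true_ccc
  )
}

# Informant report with a given number of symptomatic items per subscale.
make_report <- function(n_inatt = 0, n_hyper = 0, asq = 0, score = 2L) {
  list(
    inattention = c(rep(score, n_inatt), rep(0L, 9 - n_inatt)),
    hyperactivity = c(rep(score, n_hyper), rep(0L, 9 - n_hyper)),
    asq = asq
  )
}

# Feature table for one two-group population of the default fixture,
# standardized over that population, positive (more-affected) class first.
fixture_features <- function(groups) {
  fx <- default_fixture()
  sel <- fx$cohort[fx$cohort$group %in% groups, , drop = FALSE]
  f <- build_features(fx$effects, fx$capacity, sel)
  f$group <- factor(as.character(f$group), levels = groups)
  f
}
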