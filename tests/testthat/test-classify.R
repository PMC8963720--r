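# Feature assembly, chance levels, repeated CV, cross-prediction, and
# feature-set comparison.

toy_features <- function(n_pos = 20, n_neg = 20, shift = 0, seed = 1,
                         p = 3) {
  set.seed(seed)
  x <- matrix(rnorm((n_pos + n_neg) * p), ncol = p)
  x[seq_len(n_pos), 1] <- x[seq_len(n_pos), 1] + shift
  d <- as.data.frame(x)
  names(d) <- paste0("f", seq_len(p))
  d$group <- factor(rep(c("case", "control"), c(n_pos, n_neg)),
    levels = c("case", "control")
  )
  d
}

test_that("chance levels reproduce all five study entries", {
  expect_equal(round(chance_level(39, 36), 3), 0.520)
  expect_equal(round(chance_level(34, 36), 3), 0.486)
  expect_equal(round(chance_level(39, 34), 3), 0.534)
  # the two cross-classifications reuse the testing population's prevalence
  expect_equal(round(chance_level(34, 36), 3), 0.486)
  expect_equal(round(chance_level(39, 36), 3), 0.520)
  expect_error(chance_level(0, 5), "positive")
})

test_that("feature assembly standardizes over the stated population", {
  fx <- default_fixture()
  f <- fixture_features(c("ADHD", "TD"))
  for (col in c("alerting_rt", "orienting_rt", "conflict_rt", "overall_rt", "ccc_bps")) {
    expect_equal(mean(f[[col]]), 0, tolerance = 1e-10)
    expect_equal(sd(f[[col]]), 1, tolerance = 1e-10)
  }
  # separate populations are standardized separately
  f2 <- fixture_features(c("subthreshold", "TD"))
  expect_false(isTRUE(all.equal(
    attr(f, "center")["overall_rt"], attr(f2, "center")["overall_rt"]
  )))
  shared <- intersect(f$subject_id, f2$subject_id)
  expect_gt(length(shared), 0) # TD subjects appear in both, scaled differently
})

test_that("zero-variance features are rejected", {
  fx <- default_fixture()
  eff <- fx$effects
  eff$alerting_rt <- 1
  sel <- fx$cohort[fx$cohort$group %in% c("ADHD", "TD"), ]
  expect_error(build_features(eff, fx$capacity, sel), "zero-variance")
})

test_that("well-separated classes are classified almost perfectly", {
  f <- toy_features(shift = 8, seed = 2)
  res <- repeated_cv(f, n_repeats = 50, seed = 3)
  expect_gte(res$mean_accuracy, 0.99)
  expect_lt(res$p, 0.001)
})

test_that("repeated CV is deterministic under a fixed seed", {
  f <- toy_features(shift = 1, seed = 4)
  a <- repeated_cv(f, n_repeats = 30, seed = 5)
  b <- repeated_cv(f, n_repeats = 30, seed = 5)
  expect_identical(a$accuracy, b$accuracy)
  expect_identical(a$baseline, b$baseline)
  # column order of the features must not matter
  f_rev <- f[, c(paste0("f", 3:1), "group")]
  c_res <- repeated_cv(f_rev, n_repeats = 30, seed = 5)
  expect_equal(c_res$accuracy, a$accuracy)
})

test_that("label-free data classify at the shuffled-label expectation", {
  f <- toy_features(n_pos = 25, n_neg = 25, shift = 0, seed = 6)
  # permuting training labels destroys any signal
  set.seed(7)
  f$group <- sample(f$group)
  res <- repeated_cv(f, n_repeats = 300, seed = 8)
  # Monte-Carlo expectation of accuracy under shuffling is the baseline mean
  expect_lt(
    abs(res$mean_accuracy - res$mean_baseline),
    2 * sd(res$accuracy) / sqrt(length(res$accuracy)) + 0.05
  )
  expect_gt(res$p, 0.01)
})

test_that("k-fold mode averages ten folds per repeat", {
  f <- toy_features(shift = 2, seed = 9)
  res <- repeated_cv(f, n_repeats = 20, seed = 10, mode = "kfold")
  expect_length(res$accuracy, 20)
  expect_gt(res$mean_accuracy, res$chance_level)
  expect_true(all(res$accuracy >= 0 & res$accuracy <= 1))
})

test_that("fold-wise scaling option runs and stays near whole-sample scaling", {
  f <- toy_features(shift = 2, seed = 11)
  a <- repeated_cv(f, n_repeats = 100, seed = 12)
  b <- repeated_cv(f, n_repeats = 100, seed = 12, scale_in_folds = TRUE)
  expect_lt(abs(a$mean_accuracy - b$mean_accuracy), 0.1)
})

test_that("cross-population prediction generalizes shared feature shifts", {
  # two clinical populations sharing the same shift against controls
  train <- toy_features(n_pos = 30, n_neg = 30, shift = 3, seed = 13)
  test <- toy_features(n_pos = 28, n_neg = 30, shift = 3, seed = 14)
  levels(train$group) <- levels(test$group) <- c("caseA", "control")
  test$group <- factor(
    ifelse(test$group == "caseA", "caseB", "control"),
    levels = c("caseB", "control")
  )
  cross <- cross_classify(train, test,
    positive_levels = c("caseA", "caseB"),
    n_repeats = 200, seed = 15
  )
  direct <- repeated_cv(test, n_repeats = 200, seed = 15)
  expect_lt(abs(cross$mean_accuracy - direct$mean_accuracy), 0.1)
  expect_lt(cross$p, 0.001)

  # identical train and test populations: prediction reduces to evaluating
  # the training-set fit on random subsets
  self <- cross_classify(train, train,
    positive_levels = c("caseA", "caseA"),
    n_repeats = 100, seed = 16
  )
  fit_acc <- mean(
    predict(
      e1071::svm(as.matrix(train[, 1:3]), train$group,
        kernel = "linear", cost = 1, scale = FALSE
      ),
      as.matrix(train[, 1:3])
    ) == train$group
  )
  expect_equal(self$mean_accuracy, fit_acc, tolerance = 0.05)
})

test_that("shuffled test labels bring cross-prediction to chance", {
  train <- toy_features(n_pos = 30, n_neg = 30, shift = 3, seed = 17)
  test <- toy_features(n_pos = 30, n_neg = 30, shift = 3, seed = 18)
  set.seed(19)
  test$group <- sample(test$group)
  res <- cross_classify(test, test,
    positive_levels = c("case", "case"),
    n_repeats = 150, seed = 20
  )
  expect_lt(abs(res$mean_accuracy - 0.5), 0.1)
})

test_that("feature-set comparison is a two-sample t test", {
  f <- toy_features(shift = 2, seed = 21)
  a <- repeated_cv(f, n_repeats = 40, seed = 22)
  expect_equal(compare_feature_sets(a, a)$t, 0)

  # constructed vectors with known means and SD follow the hand formula
  mk <- function(mean_target, n) {
    v <- scale(rnorm(n))[, 1] * 0.02 + mean_target
    a2 <- a
    a2$accuracy <- v
    a2
  }
  set.seed(23)
  ra <- mk(0.65, 1000)
  rb <- mk(0.60, 1000)
  res <- compare_feature_sets(ra, rb)
  se <- sqrt(0.02^2 / 1000 + 0.02^2 / 1000)
  expect_equal(res$t, (mean(ra$accuracy) - mean(rb$accuracy)) / se,
    tolerance = 1e-6
  )
  expect_equal(res$t, -compare_feature_sets(rb, ra)$t)
  b <- repeated_cv(f, n_repeats = 39, seed = 24)
  expect_error(compare_feature_sets(a, b), "equal length")
})
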